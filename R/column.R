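# Soil column discretization: three organic horizons resolved into 1-cm
# layers with per-horizon hydraulic, bulk-density, and initial-SOC
# properties.  The mineral soil below the organic column is not modeled.

#' Horizon specification
#'
#' @param name Horizon label; one of `"dead_moss_slightly_decomposed"`,
#'   `"moderately_decomposed"`, `"well_decomposed"` (free-form labels are
#'   allowed for custom columns).
#' @param thickness Horizon thickness (cm); must be a positive whole
#'   multiple of the layer thickness.
#' @param vg A [vg_params()] object.
#' @param rho_b Bulk density (g cm^-3).
#' @param soc_density Initial SOC per layer (g C cm^-2); scalar or one
#'   value per layer of the horizon.
#' @return An object of class `horizon_spec`.
#' @export
horizon_spec <- function(name, thickness, vg, rho_b, soc_density) {
  stopifnot(inherits(vg, "vg_params"), thickness > 0, rho_b > 0,
            all(soc_density >= 0))
  structure(list(name = name, thickness = thickness, vg = vg,
                 rho_b = rho_b, soc_density = soc_density),
            class = "horizon_spec")
}

#' Default hydraulic parameter table for organic horizons
#'
#' Per-horizon Mualem-van Genuchten parameters for boreal organic soil
#' horizons.  The dead-moss, moderately decomposed, and well decomposed
#' rows are only physically admissible (theta_r < theta_s, n > 1) when the
#' four published values are read in the order (K_sat, theta_r, theta_s,
#' n); that ordering is adopted here and validated at construction.  The
#' live-moss row (K_sat 1017.4, n 2.38, theta_r 0.04, theta_s 0.95) sits
#' above the simulated column and is included for reference only.
#'
#' @return A data.frame keyed by horizon name with columns `K_sat`,
#'   `theta_r`, `theta_s`, `n`, `alpha_vg`, `rho_b`.
#' @export
default_horizon_table <- function() {
  data.frame(
    name    = c("live_moss", "dead_moss_slightly_decomposed",
                "moderately_decomposed", "well_decomposed"),
    K_sat   = c(1017.4, 100.8, 0.716, 0.036),
    theta_r = c(0.04, 0.01, 0.18, 0.22),
    theta_s = c(0.95, 0.93, 0.88, 0.83),
    n       = c(2.38, 1.9, 1.7, 1.6),
    alpha_vg = c(0.1, 0.1, 0.1, 0.1),
    rho_b   = c(0.02, 0.03, 0.07, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Assemble a 1-cm-layered soil column from horizon specifications
#'
#' @param horizons A list of [horizon_spec()] objects, ordered from the
#'   surface downward.
#' @param dx Layer thickness (cm); default 1.
#' @return An object of class `soil_column` with a per-layer property
#'   table (`$layers`), the layer count, total thickness `L`, and
#'   layer-center depth grid (cm, positive downward).
#' @export
soil_column <- function(horizons, dx = 1) {
  stopifnot(length(horizons) >= 1,
            all(vapply(horizons, inherits, TRUE, "horizon_spec")))
  rows <- lapply(horizons, function(hz) {
    nl <- hz$thickness / dx
    if (abs(nl - round(nl)) > 1e-9 || nl < 1)
      stop("horizon thickness must be a positive whole number of layers: ",
           hz$name)
    nl <- round(nl)
    soc <- if (length(hz$soc_density) == 1) rep(hz$soc_density, nl)
           else if (length(hz$soc_density) == nl) hz$soc_density
           else stop("soc_density must be scalar or one value per layer: ",
                     hz$name)
    data.frame(horizon = hz$name,
               K_sat = hz$vg$K_sat, theta_r = hz$vg$theta_r,
               theta_s = hz$vg$theta_s, n = hz$vg$n, m = hz$vg$m,
               l = hz$vg$l, alpha_vg = hz$vg$alpha_vg,
               rho_b = hz$rho_b, soc0 = soc,
               stringsAsFactors = FALSE)
  })
  layers <- do.call(rbind, rows)
  n <- nrow(layers)
  layers$depth <- (seq_len(n) - 0.5) * dx
  structure(list(layers = layers, n_layers = n, dx = dx, L = n * dx),
            class = "soil_column")
}

# Per-layer vg_params view of a column (vectorized fields).
column_vg <- function(column) {
  lay <- column$layers
  structure(list(K_sat = lay$K_sat, theta_r = lay$theta_r,
                 theta_s = lay$theta_s, n = lay$n, m = lay$m,
                 l = lay$l, alpha_vg = lay$alpha_vg),
            class = "vg_params")
}

#' @export
print.soil_column <- function(x, ...) {
  cat("<soil_column> ", x$n_layers, " layers x ", x$dx, " cm (L = ",
      x$L, " cm)\n", sep = "")
  hz <- rle(x$layers$horizon)
  for (i in seq_along(hz$values))
    cat("  ", hz$values[i], ": ", hz$lengths[i] * x$dx, " cm\n", sep = "")
  cat("  total initial SOC: ",
      formatC(sum(x$layers$soc0) * 1e4, digits = 4, format = "fg"),
      " g C m-2\n", sep = "")
  invisible(x)
}

#' Build a column for a site archetype
#'
#' Splits the archetype's organic-horizon thickness across the three
#' organic horizons and assigns hydraulic parameters from a horizon table.
#' The default initial SOC density is `c_frac * rho_b * dx` per layer
#' (organic-horizon material is roughly `c_frac` = 45% carbon by mass),
#' which increases with depth through the bulk-density profile.
#'
#' @param archetype A [site_archetype()].
#' @param hydraulic_config A horizon parameter table in the format of
#'   [default_horizon_table()].
#' @param thicknesses Named vector of horizon thicknesses (cm); defaults
#'   depend on the archetype and sum to its organic thickness.
#' @param c_frac Carbon mass fraction of organic-horizon material used for
#'   the default SOC profile.
#' @param soc_total Optional total initial SOC (g C m^-2) to which the
#'   default profile is rescaled.
#' @param dx Layer thickness (cm).
#' @return A [soil_column()].
#' @export
generate_column <- function(archetype, hydraulic_config = default_horizon_table(),
                            thicknesses = NULL, c_frac = 0.45,
                            soc_total = NULL, dx = 1) {
  stopifnot(inherits(archetype, "site_archetype"))
  if (is.null(thicknesses)) {
    # WD: 2 cm dead moss + litter, 1 cm slightly decomposed, 6 cm
    # moderately decomposed (the published profile), padded to the 10-cm
    # organic mat.  MWDp: 2 cm dead moss + litter over a column dominated
    # by amorphous (sapric) and well-decomposed material with charcoal,
    # which is hydraulically the low-conductivity well-decomposed class.
    thicknesses <- if (archetype$name == "WD")
      c(dead_moss_slightly_decomposed = 3, moderately_decomposed = 6,
        well_decomposed = 1)
    else
      c(dead_moss_slightly_decomposed = 2, moderately_decomposed = 2,
        well_decomposed = 16)
  }
  if (abs(sum(thicknesses) - archetype$organic_thickness) > 1e-9)
    stop("horizon thicknesses must sum to the archetype organic thickness (",
         archetype$organic_thickness, " cm)")
  horizons <- lapply(names(thicknesses), function(nm) {
    row <- hydraulic_config[hydraulic_config$name == nm, ]
    if (nrow(row) != 1) stop("no hydraulic parameters for horizon: ", nm)
    horizon_spec(nm, thicknesses[[nm]],
                 vg_params(row$K_sat, row$theta_r, row$theta_s, row$n,
                           alpha_vg = row$alpha_vg),
                 rho_b = row$rho_b,
                 soc_density = c_frac * row$rho_b * dx)
  })
  col <- soil_column(horizons, dx = dx)
  if (!is.null(soc_total)) {
    cur <- sum(col$layers$soc0) * 1e4
    col$layers$soc0 <- col$layers$soc0 * (soc_total / cur)
  }
  col
}
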