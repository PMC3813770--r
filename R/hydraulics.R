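# Unsaturated hydraulics of the organic column: Mualem-van Genuchten
# retention/conductivity, Darcy-type water flux diagnosed from a prescribed
# moisture profile (no Richards solve), and pore-water velocity.

#' Mualem-van Genuchten hydraulic parameter set
#'
#' Bundles the retention and conductivity parameters of a soil horizon.
#' The shape exponent `m` defaults to the Mualem constraint `m = 1 - 1/n`,
#' and the pore-connectivity parameter `l` to 0.5.
#'
#' @param K_sat Saturated hydraulic conductivity (cm h^-1).
#' @param theta_r Residual volumetric moisture (cm^3 cm^-3).
#' @param theta_s Saturated volumetric moisture (cm^3 cm^-3).
#' @param n Pore-size distribution exponent (unitless, > 1).
#' @param alpha_vg Retention scale parameter (cm^-1).
#' @param m Pore-size shape exponent; default `1 - 1/n`.
#' @param l Pore-connectivity exponent; default 0.5.
#' @return An object of class `vg_params`.
#' @examples
#' vg <- vg_params(K_sat = 100.8, theta_r = 0.01, theta_s = 0.93, n = 1.9)
#' hydraulic_conductivity(0.93, vg)  # == K_sat at saturation
#' @export
vg_params <- function(K_sat, theta_r, theta_s, n, alpha_vg = 0.1,
                      m = 1 - 1 / n, l = 0.5) {
  stopifnot(is.numeric(K_sat), is.numeric(theta_r), is.numeric(theta_s))
  if (any(K_sat <= 0)) stop("K_sat must be positive")
  if (any(theta_r >= theta_s))
    stop("degenerate retention parameters: theta_r must be < theta_s")
  if (any(n <= 1)) stop("van Genuchten n must exceed 1")
  if (any(m <= 0 | m >= 1)) stop("van Genuchten m must lie in (0, 1)")
  if (any(alpha_vg <= 0)) stop("alpha_vg must be positive")
  structure(list(K_sat = K_sat, theta_r = theta_r, theta_s = theta_s,
                 n = n, m = m, l = l, alpha_vg = alpha_vg),
            class = "vg_params")
}

#' Effective saturation
#'
#' `Se = (theta - theta_r) / (theta_s - theta_r)`, clamped to `[0, 1]`
#' with a warning when `theta` falls outside the admissible range.
#'
#' @param theta Volumetric moisture (cm^3 cm^-3); vectorized.
#' @param vg A [vg_params()] object (fields may be vectors matching `theta`).
#' @return Effective saturation in `[0, 1]`.
#' @export
effective_saturation <- function(theta, vg) {
  span <- vg$theta_s - vg$theta_r
  if (any(span <= 0)) stop("degenerate retention parameters: theta_s == theta_r")
  se <- (theta - vg$theta_r) / span
  if (any(se < -1e-12 | se > 1 + 1e-12))
    warning("moisture outside [theta_r, theta_s]; clamped")
  pmin(pmax(se, 0), 1)
}

#' Unsaturated hydraulic conductivity (Mualem-van Genuchten)
#'
#' `K(theta) = K_sat * Se^l * (1 - (1 - Se^(1/m))^m)^2`.  Equals `K_sat`
#' at saturation and 0 at residual moisture, and is nondecreasing in
#' `theta`.
#'
#' @inheritParams effective_saturation
#' @return Conductivity (cm h^-1).
#' @export
hydraulic_conductivity <- function(theta, vg) {
  se <- effective_saturation(theta, vg)
  mob <- 1 - (1 - se^(1 / vg$m))^vg$m
  vg$K_sat * se^vg$l * mob^2
}

#' Matric potential from moisture (inverted van Genuchten retention)
#'
#' Inverts `Se = (1 + (alpha_vg * |h|)^n)^(-m)` to
#' `h = -(1/alpha_vg) * (Se^(-1/m) - 1)^(1/n)`.  Zero at saturation,
#' strictly monotone on `(theta_r, theta_s]`, and diverging to `-Inf`
#' as `theta` approaches `theta_r` (an error is signalled at or below
#' `theta_r`, where the potential is undefined).
#'
#' @inheritParams effective_saturation
#' @return Matric potential `h` (cm, <= 0).
#' @export
matric_potential <- function(theta, vg) {
  if (any(theta <= vg$theta_r))
    stop("matric potential undefined at or below residual moisture")
  se <- effective_saturation(theta, vg)
  -(1 / vg$alpha_vg) * (se^(-1 / vg$m) - 1)^(1 / vg$n)
}

#' Moisture from matric potential (forward van Genuchten retention)
#'
#' @param h Matric potential (cm, <= 0).
#' @param vg A [vg_params()] object.
#' @return Volumetric moisture (cm^3 cm^-3).
#' @export
retention_moisture <- function(h, vg) {
  se <- (1 + (vg$alpha_vg * abs(pmin(h, 0)))^vg$n)^(-vg$m)
  vg$theta_r + se * (vg$theta_s - vg$theta_r)
}

#' Darcy-type water flux at layer interfaces
#'
#' Diagnoses the unsaturated water flux density from a prescribed moisture
#' profile: `J_w = K * (1 - dh/dx)` with depth `x` positive downward, so a
#' uniform profile drains at `J_w = K(theta)` (pure gravity) and the
#' hydrostatic profile `h = x - L` carries zero flux.  Interface
#' conductivity uses a configurable averaging rule (geometric mean by
#' default; the arithmetic and upstream alternatives are provided because
#' no rule is canonical for layered organic soils).
#'
#' @param theta_profile Moisture per layer, aligned with `column`.
#' @param column A [soil_column()].
#' @param bottom_bc `"free_drainage"` (unit gradient, `J = K_n`) or
#'   `"impermeable"` (zero flux, e.g. permafrost below the column).  With
#'   an impermeable base, interfaces between saturated layers also carry
#'   zero flux: moisture carries no pressure information at saturation,
#'   and a saturated zone ponded on a no-flow boundary is stagnant.
#' @param interface_mean One of `"geometric"`, `"arithmetic"`, `"upstream"`.
#' @return Numeric vector of length `n_layers + 1`: downward-positive flux
#'   (cm h^-1) at the top surface, each interior interface, and the base.
#'   The top value assumes a zero moisture gradient above the first layer.
#' @export
water_flux <- function(theta_profile, column,
                       bottom_bc = c("free_drainage", "impermeable"),
                       interface_mean = c("geometric", "arithmetic", "upstream")) {
  bottom_bc <- match.arg(bottom_bc)
  interface_mean <- match.arg(interface_mean)
  n <- column$n_layers
  if (length(theta_profile) != n)
    stop("moisture profile does not match the column grid")
  lay <- column$layers
  vg <- column_vg(column)
  dx <- column$dx

  theta <- pmin(pmax(theta_profile, lay$theta_r + 1e-9), lay$theta_s)
  K <- hydraulic_conductivity(theta, vg)
  h <- matric_potential(pmax(theta, lay$theta_r + 1e-6), vg)

  J <- numeric(n + 1)
  if (n >= 2) {
    i <- seq_len(n - 1)
    Kf <- switch(interface_mean,
                 geometric  = sqrt(K[i] * K[i + 1]),
                 arithmetic = (K[i] + K[i + 1]) / 2,
                 upstream   = K[i])
    dhdx <- (h[i + 1] - h[i]) / dx
    J[i + 1] <- Kf * (1 - dhdx)
  }
  J[1] <- K[1]
  J[n + 1] <- if (bottom_bc == "free_drainage") K[n] else 0
  if (bottom_bc == "impermeable" && n >= 2) {
    se <- effective_saturation(theta, vg)
    sat <- se > 0.995
    both_sat <- sat[-n] & sat[-1]
    J[which(both_sat) + 1] <- 0
  }
  J
}

#' Moisture at a prescribed drainage flux (field-capacity inversion)
#'
#' Solves `K(theta) = q` for `theta`: the moisture at which a freely
#' draining profile passes the climatological recharge `q` under a unit
#' gradient.  Vectorized over the per-layer parameters of a column-style
#' `vg_params`.
#'
#' @param q Target flux (cm h^-1); scalar or per layer.
#' @param vg A [vg_params()] (possibly vector-valued fields).
#' @return Volumetric moisture per layer.
#' @export
moisture_at_flux <- function(q, vg) {
  n <- max(lengths(unclass(vg)))
  q <- rep_len(q, n)
  vapply(seq_len(n), function(i) {
    vgi <- vg_params(vg$K_sat[min(i, length(vg$K_sat))],
                     vg$theta_r[min(i, length(vg$theta_r))],
                     vg$theta_s[min(i, length(vg$theta_s))],
                     vg$n[min(i, length(vg$n))],
                     alpha_vg = vg$alpha_vg[min(i, length(vg$alpha_vg))],
                     m = vg$m[min(i, length(vg$m))],
                     l = vg$l[min(i, length(vg$l))])
    if (q[i] >= vgi$K_sat) return(vgi$theta_s)
    f <- function(se) {
      th <- vgi$theta_r + se * (vgi$theta_s - vgi$theta_r)
      hydraulic_conductivity(th, vgi) - q[i]
    }
    se <- stats::uniroot(f, c(1e-9, 1), tol = 1e-12)$root
    vgi$theta_r + se * (vgi$theta_s - vgi$theta_r)
  }, numeric(1))
}

#' Steady uniform-drainage moisture profile
#'
#' Moisture profile of a column draining at a steady flux `q`: the
#' matric head solves `dh/dx = 1 - q/K(h)` (depth `x` positive down),
#' integrated upward from the bottom horizon's field capacity
#' (`K(h) = q`, unit gradient), so the head is continuous across horizon
#' boundaries and the Darcy flux equals `q` at every interface.  This is
#' the baseline state of the well-drained archetype, with `q` set by
#' climatological recharge.
#'
#' @param column A [soil_column()].
#' @param q Steady drainage flux (cm h^-1).
#' @param dz Integration step (cm).
#' @return Volumetric moisture at the layer centers.
#' @export
steady_moisture_profile <- function(column, q, dz = NULL) {
  lay <- column$layers
  n <- column$n_layers
  dx <- column$dx
  layer_vg <- function(i)
    vg_params(lay$K_sat[i], lay$theta_r[i], lay$theta_s[i], lay$n[i],
              alpha_vg = lay$alpha_vg[i], m = lay$m[i], l = lay$l[i])
  Kh <- function(h, vg) hydraulic_conductivity(retention_moisture(h, vg), vg)
  # Field capacity of the bottom layer anchors the march; each interface
  # then solves the DISCRETE flux relation (geometric-mean conductivity,
  # the water_flux default) for the layer-center head above, so the
  # diagnosed interface fluxes equal q exactly, including across horizon
  # boundaries.
  h <- numeric(n)
  vgn <- layer_vg(n)
  h[n] <- matric_potential(max(moisture_at_flux(q, vgn),
                               vgn$theta_r + 1e-9), vgn)
  for (i in seq(n - 1, 1)) {
    vgi <- layer_vg(i)
    vgb <- layer_vg(i + 1)
    f <- function(hi)
      sqrt(Kh(hi, vgi) * Kh(h[i + 1], vgb)) *
        (1 - (h[i + 1] - hi) / dx) - q
    lo <- h[i + 1] - 5 * dx
    while (f(lo) > 0 && lo > -1e6) lo <- lo * 2 - dx
    hi <- stats::uniroot(f, c(lo, 0), tol = 1e-12)$root
    h[i] <- hi
  }
  vapply(seq_len(n), function(i) retention_moisture(h[i], layer_vg(i)),
         numeric(1))
}

#' Pore-water velocity
#'
#' `v = J_w / theta`.  Moisture below a configurable floor (default
#' `max(theta_r + 1e-4, 1e-3)`) is treated as the floor value so that
#' near-dry layers cannot produce unbounded velocities; a warning reports
#' the cap.
#'
#' @param J_w Water flux density (cm h^-1); vectorized.
#' @param theta Volumetric moisture at the same locations.
#' @param theta_floor Lower moisture bound used in the division.
#' @return Pore-water velocity (cm h^-1).
#' @export
pore_water_velocity <- function(J_w, theta, theta_floor = 1e-3) {
  low <- theta < theta_floor
  if (any(low & J_w != 0))
    warning("moisture at or below the velocity floor; velocity capped")
  v <- J_w / pmax(theta, theta_floor)
  v[J_w == 0] <- 0
  v
}
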