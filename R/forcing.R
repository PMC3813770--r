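# Synthetic hourly forcing for two boreal black spruce site archetypes.
# Stands in for unavailable hourly sensor records: seasonal + diurnal
# temperature cycles damped with depth, and bounded moisture trajectories
# with episodic wetting, clamped to each horizon's [theta_r, theta_s].

# Run code under a temporary RNG state so generators are pure given a seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Site archetype
#'
#' Bundles the site-level quantities that drive an experiment: organic
#' horizon thickness, annual NPP (the basis of pulsed DOC input), the
#' belowground-NPP SOC input, the moisture regime, and the statistical
#' settings of the synthetic forcing generator.  Defaults: WD (well
#' drained, no permafrost): 10 cm organic horizon, NPP 268 and SOC input
#' 134 g C m^-2 yr^-1, unsaturated; MWDp (moderately well drained over
#' permafrost): 20 cm, NPP 250, SOC input 116, wet at depth with impeded
#' drainage.
#'
#' @param name `"WD"` or `"MWDp"`.
#' @param organic_thickness,npp,i_soc,moisture_regime,temperature_stats
#'   Overrides for the archetype defaults (see Details in the vignette).
#' @return An object of class `site_archetype`.
#' @export
site_archetype <- function(name = c("WD", "MWDp"), organic_thickness = NULL,
                           npp = NULL, i_soc = NULL, moisture_regime = NULL,
                           temperature_stats = NULL) {
  name <- match.arg(name)
  def <- if (name == "WD") {
    list(organic_thickness = 10, npp = 268, i_soc = 134,
         moisture_regime = "unsaturated",
         temperature_stats = list(surface_mean = 9, seasonal_amp = 5,
                                  diurnal_amp = 4, grad = -0.15,
                                  z_seasonal = 25, z_diurnal = 6,
                                  noise_sd = 1.2, noise_rho = 0.95),
         moisture_stats = list(recharge = 0.005, wet_rate = 1 / 120,
                               wet_jump = c(0.1, 0.3), dry_decay = 0.995,
                               z_wet = 8, wet_span = 0.5))
  } else {
    list(organic_thickness = 20, npp = 250, i_soc = 116,
         moisture_regime = "saturated_at_depth",
         temperature_stats = list(surface_mean = 7, seasonal_amp = 4,
                                  diurnal_amp = 3, grad = -0.3,
                                  z_seasonal = 25, z_diurnal = 6,
                                  noise_sd = 1.0, noise_rho = 0.95),
         moisture_stats = list(base_sat = 0.55, wet_rate = 1 / 120,
                               wet_jump = c(0.1, 0.25), dry_decay = 0.997,
                               z_wet = 8, sat_depth_frac = 0.5,
                               wt_amp = 3))
  }
  if (!is.null(organic_thickness)) def$organic_thickness <- organic_thickness
  if (!is.null(npp)) def$npp <- npp
  if (!is.null(i_soc)) def$i_soc <- i_soc
  if (!is.null(moisture_regime)) def$moisture_regime <- moisture_regime
  if (!is.null(temperature_stats))
    def$temperature_stats <- utils::modifyList(def$temperature_stats,
                                               temperature_stats)
  if (def$organic_thickness <= 0 || def$npp <= 0 || def$i_soc <= 0)
    stop("thickness and rates must be positive")
  structure(c(list(name = name), def), class = "site_archetype")
}

#' Generate seeded hourly forcing for a column
#'
#' Temperature: site mean + linear depth gradient + seasonal sinusoid
#' (peaking mid-season) and diurnal cycle, both damped exponentially with
#' depth, plus AR(1) noise damped with depth.  Moisture: per-layer
#' baseline saturation plus a shared wetting state (episodic rain events,
#' exponential drydown) attenuated with depth, clamped to
#' `[theta_r + margin, theta_s]`; for MWDp the lower fraction of the
#' column is held near saturation.  Bit-identical for a given
#' `(archetype, column, seed)`.
#'
#' @param archetype A [site_archetype()].
#' @param column A [soil_column()].
#' @param seed Integer seed.
#' @param hours Number of hourly records (default one growing season).
#' @return An object of class `doc_forcing`: list with `time` (h, from 0),
#'   matrices `T` and `M` (`hours x n_layers`), and the layer depths.
#' @export
generate_forcing <- function(archetype, column, seed,
                             hours = SEASON_HOURS) {
  stopifnot(inherits(archetype, "site_archetype"),
            inherits(column, "soil_column"))
  n <- column$n_layers
  z <- column$layers$depth
  ts <- archetype$temperature_stats
  ms <- archetype$moisture_stats
  lay <- column$layers
  with_seed(seed, {
    t_h <- seq_len(hours) - 1
    day <- t_h / 24
    seas <- cos(2 * pi * (day - 76) / 365)       # peak near mid-July
    diur <- sin(2 * pi * (t_h %% 24 - 8) / 24)   # warmest mid-afternoon
    noise <- stats::filter(stats::rnorm(hours, 0, ts$noise_sd),
                           ts$noise_rho, method = "recursive")
    noise <- as.numeric(noise) * sqrt(1 - ts$noise_rho^2)
    Tm <- outer(rep(1, hours), ts$surface_mean + ts$grad * z) +
      outer(ts$seasonal_amp * seas, exp(-z / ts$z_seasonal)) +
      outer(ts$diurnal_amp * diur, exp(-z / ts$z_diurnal)) +
      outer(noise, exp(-z / 10))

    # Shared wetting state: jumps at Poisson-type events, slow drydown.
    events <- stats::runif(hours) < ms$wet_rate
    jumps <- ifelse(events,
                    stats::runif(hours, ms$wet_jump[1], ms$wet_jump[2]), 0)
    w <- numeric(hours)
    wcur <- 0.1
    for (i in seq_len(hours)) {
      wcur <- wcur * ms$dry_decay + jumps[i]
      w[i] <- min(wcur, 1)
    }
    span <- lay$theta_s - lay$theta_r
    if (identical(archetype$moisture_regime, "saturated_at_depth")) {
      # Poorly drained: moisture follows a hydrostatic profile above a
      # fluctuating water table (h = depth - z_wt), so the diagnosed
      # Darcy flux is near zero -- the defining feature of the site.
      z_wt <- ms$sat_depth_frac * column$L - ms$wt_amp * w
      vg <- column_vg(column)
      Mm <- t(vapply(z_wt, function(wt)
        retention_moisture(pmin(z - wt, 0), vg), numeric(n)))
    } else {
      # Well-drained: the baseline is the field-capacity moisture at
      # which unit-gradient drainage matches climatological recharge
      # (so seasonal water throughput is consistent with precipitation);
      # wetting events push the profile transiently wetter.
      base <- steady_moisture_profile(column, ms$recharge)
      Mm <- outer(rep(1, hours), base) +
        outer(w, exp(-z / ms$z_wet)) *
          outer(rep(1, hours), ms$wet_span * (lay$theta_s - base))
    }
    lo <- lay$theta_r + 0.02 * span
    Mm <- pmin(pmax(Mm, rep(lo, each = hours)),
               rep(lay$theta_s, each = hours))
    structure(list(time = t_h, T = Tm, M = Mm, depth = z,
                   archetype = archetype$name, seed = seed),
              class = "doc_forcing")
  })
}

#' Annual-mean forcing profiles for spin-up
#'
#' Constant per-layer temperature and moisture representative of the
#' annual mean (colder than the growing season; the sites' mean annual
#' air temperature is about -2.3 degC, buffered in the organic mat).
#'
#' @inheritParams generate_forcing
#' @param t_surface Annual-mean surface soil temperature (degC).
#' @return List with per-layer vectors `T` and `M`.
#' @export
forcing_annual_mean <- function(archetype, column, t_surface = 1) {
  z <- column$layers$depth
  lay <- column$layers
  ms <- archetype$moisture_stats
  span <- lay$theta_s - lay$theta_r
  if (identical(archetype$moisture_regime, "saturated_at_depth")) {
    z_wt <- ms$sat_depth_frac * column$L
    M <- retention_moisture(pmin(z - z_wt, 0), column_vg(column))
    M <- pmax(M, lay$theta_r + 0.02 * span)
  } else {
    M <- steady_moisture_profile(column, ms$recharge)
  }
  list(T = t_surface + archetype$temperature_stats$grad * z, M = M)
}

#' Write / read forcing as long-format CSV
#'
#' Canonical interchange schema: columns `time_h`, `depth_cm`, `T_C`,
#' `theta`, sorted by time then depth.  `read_forcing()` validates that
#' the time axis is gap-free and, when a column is supplied, that the
#' depth axis matches its layer centers.
#'
#' @param forcing A `doc_forcing`.
#' @param path File path.
#' @return `write_forcing()` returns `path` invisibly; `read_forcing()`
#'   returns a `doc_forcing`.
#' @export
write_forcing <- function(forcing, path) {
  n <- length(forcing$depth)
  df <- data.frame(
    time_h = rep(forcing$time, each = n),
    depth_cm = rep(forcing$depth, times = length(forcing$time)),
    T_C = as.vector(t(forcing$T)),
    theta = as.vector(t(forcing$M))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_forcing
#' @param column Optional [soil_column()] to validate the depth axis
#'   against.
#' @export
read_forcing <- function(path, column = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_h", "depth_cm", "T_C", "theta")
  if (!all(need %in% names(df)))
    stop("forcing file must have columns: ", paste(need, collapse = ", "))
  times <- sort(unique(df$time_h))
  if (length(times) > 1 && any(diff(times) != diff(times)[1]))
    stop("forcing time axis has gaps or irregular spacing")
  depths <- sort(unique(df$depth_cm))
  if (!is.null(column) &&
      !isTRUE(all.equal(depths, column$layers$depth, tolerance = 1e-8)))
    stop("forcing depths do not match the column grid; resample first ",
         "(see resample_forcing)")
  df <- df[order(df$time_h, df$depth_cm), ]
  nt <- length(times); nd <- length(depths)
  if (nrow(df) != nt * nd) stop("forcing grid is incomplete")
  structure(list(time = times,
                 T = matrix(df$T_C, nrow = nt, ncol = nd, byrow = TRUE),
                 M = matrix(df$theta, nrow = nt, ncol = nd, byrow = TRUE),
                 depth = depths, archetype = NA_character_, seed = NA),
            class = "doc_forcing")
}

#' Resample forcing from sensor depths onto a column grid
#'
#' Linear interpolation between sensor depths with constant extrapolation
#' beyond the shallowest/deepest sensor -- the ingestion path any user of
#' real sensor records (measured at a few depths only) must take.
#'
#' @param forcing A `doc_forcing` defined at arbitrary depths.
#' @param column Target [soil_column()].
#' @return A `doc_forcing` on the column's layer centers.
#' @export
resample_forcing <- function(forcing, column) {
  zt <- column$layers$depth
  interp <- function(mat) {
    t(apply(mat, 1, function(row)
      stats::approx(forcing$depth, row, xout = zt, rule = 2)$y))
  }
  structure(list(time = forcing$time, T = interp(forcing$T),
                 M = interp(forcing$M), depth = zt,
                 archetype = forcing$archetype, seed = forcing$seed),
            class = "doc_forcing")
}

#' Pulse schedule for seasonal DOC input
#'
#' Pulses fire at `t = phase, phase + period, ...` strictly before the end
#' of the season; the total seasonal input is divided equally among them.
#'
#' @param total_input Seasonal DOC input (g C m^-2).
#' @param period_h Hours between pulses (> 0).
#' @param season_h Season length (h).
#' @param phase First pulse hour (default 0).
#' @return Object of class `pulse_schedule` with `times`, `pulse_mass`
#'   (g C m^-2 each), `period_h`, `total_input`.
#' @export
pulse_schedule <- function(total_input, period_h, season_h = SEASON_HOURS,
                           phase = 0) {
  if (period_h <= 0) stop("period must be positive")
  if (total_input < 0) stop("total input must be nonnegative")
  if (period_h >= season_h) {
    warning("pulse period exceeds the season; a single pulse carries ",
            "the full input")
    times <- phase
  } else {
    times <- seq(phase, season_h - 1e-9, by = period_h)
  }
  structure(list(times = times, pulse_mass = total_input / length(times),
                 period_h = period_h, total_input = total_input,
                 season_h = season_h),
            class = "pulse_schedule")
}

#' Pulse schedule from an archetype's NPP
#'
#' Seasonal DOC input equals `fraction` of the archetype's annual NPP,
#' delivered in pulses of the given period.
#'
#' @param archetype A [site_archetype()].
#' @param fraction Fraction of annual NPP entering as DOC (e.g. 0.1, 0.3,
#'   0.5).
#' @param period_h Hours between pulses.
#' @param season_h Season length (h).
#' @return A [pulse_schedule()].
#' @export
generate_pulse_schedule <- function(archetype, fraction, period_h,
                                    season_h = SEASON_HOURS) {
  if (fraction <= 0) stop("fraction must be positive")
  pulse_schedule(fraction * archetype$npp, period_h, season_h)
}
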