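# Orchestration: state initialization, spin-up under mean forcing,
# seasonal coupled runs (transport + sorption + biology + pulses), paired
# priming experiments, warming and no-transport counterfactuals, and the
# experiment grid over input fraction x pulse period x necromass routing.
#
# Hourly operator splitting: (1) pulse deposition, (2) conservative
# transport with equilibrium (type-1) retardation folded into the storage
# term, (3) exact kinetic (type-2) exchange, (4) biological reactions with
# internal sub-steps.  Every operator conserves carbon identically, so the
# whole-run mass balance closes to machine precision and is audited.

#' Run options
#'
#' @param no_transport Zero the pore-water velocity and dispersion
#'   (the no-water-movement counterfactual).
#' @param bottom_bc Water/solute bottom boundary: `"free_drainage"` or
#'   `"impermeable"` (permafrost-impeded).
#' @param n_sub_react Biological sub-steps per hour.
#' @param n_sub_transport Minimum transport sub-steps per hour (the
#'   solver adds more under its Courant criterion).
#' @param theta_t Transport time weighting (1 = fully implicit, the
#'   monotone default; 0.5 = Crank-Nicolson).
#' @param interface_mean Interface conductivity averaging rule.
#' @param track_hourly Keep hourly column totals (for plotting).
#' @return A list of class `run_options`.
#' @export
run_options <- function(no_transport = FALSE,
                        bottom_bc = c("free_drainage", "impermeable"),
                        n_sub_react = 2, n_sub_transport = 1,
                        theta_t = 1,
                        interface_mean = c("geometric", "arithmetic",
                                           "upstream"),
                        track_hourly = FALSE) {
  structure(list(no_transport = no_transport,
                 bottom_bc = match.arg(bottom_bc),
                 n_sub_react = n_sub_react,
                 n_sub_transport = n_sub_transport,
                 theta_t = theta_t,
                 interface_mean = match.arg(interface_mean),
                 track_hourly = track_hourly),
            class = "run_options")
}

#' Initialize the carbon pool state of a column
#'
#' SOC from the column's configured profile; microbial biomass at
#' `mbc_frac` (default 3%) of SOC per layer; aqueous DOC at a configured
#' concentration; type-1 sorbed DOC in instantaneous equilibrium and
#' type-2 at its kinetic fixed point, so the sorption operator starts with
#' zero exchange flux.
#'
#' @param column A [soil_column()].
#' @param tp A [transport_params()].
#' @param doc0 Initial aqueous DOC concentration (g C mL^-1); scalar or
#'   per layer.
#' @param mbc_frac Initial biomass as a fraction of SOC.
#' @param rp A [rate_params()] supplying the initial activity `f_act`.
#' @return Object of class `pool_state`: per-layer vectors `soc`, `doc`,
#'   `pdoc1`, `pdoc2`, `mbc`, and the microbial activity state `act`.
#' @export
initialize_state <- function(column, tp = transport_params(),
                             doc0 = 5e-5, mbc_frac = 0.03,
                             rp = rate_params()) {
  soc <- column$layers$soc0
  if (is.null(soc)) stop("column has no initial SOC profile")
  n <- column$n_layers
  doc <- rep_len(doc0, n)
  structure(list(soc = soc,
                 doc = doc,
                 pdoc1 = tp$f * tp$K_d * doc,
                 pdoc2 = (1 - tp$f) * tp$K_d * doc,
                 mbc = mbc_frac * soc,
                 act = rep(rp$f_act, n)),
            class = "pool_state")
}

# Total carbon in the column, g C cm^-2.
total_carbon <- function(state, column, theta) {
  lay <- column$layers
  dx <- column$dx
  sum(state$soc) + sum(state$mbc) +
    sum(theta * state$doc * dx) +
    sum(lay$rho_b * (state$pdoc1 + state$pdoc2) * dx)
}

#' Run one growing season of the coupled model
#'
#' @param state Initial [initialize_state()] `pool_state` (typically
#'   spun up).
#' @param column A [soil_column()].
#' @param forcing A `doc_forcing` whose rows are steps of `dt` hours.
#' @param schedule A [pulse_schedule()] or `NULL` for no DOC input.
#' @param rp,tp,tm Parameter objects.
#' @param i_soc_total Seasonal external SOC input (g C m^-2), distributed
#'   uniformly over layers and steps.
#' @param options A [run_options()].
#' @param dt Step length in hours (1 for seasonal runs; spin-up uses
#'   longer steps).
#' @return Object of class `season_run`: final `state`, cumulative
#'   per-layer `ledger` (CO2 components, inputs), boundary tallies, the
#'   relative mass-balance `residual`, and (optionally) hourly totals.
#' @export
run_season <- function(state, column, forcing, schedule = NULL,
                       rp = rate_params(), tp = transport_params(),
                       tm = tm_params(), i_soc_total = 134,
                       options = run_options(), dt = 1) {
  n <- column$n_layers
  dx <- column$dx
  H <- nrow(forcing$T)
  if (ncol(forcing$T) != n || ncol(forcing$M) != n)
    stop("forcing does not cover the column layer grid")
  if (any(!is.finite(forcing$T)) || any(!is.finite(forcing$M)))
    stop("forcing contains gaps or non-finite values")
  lay <- column$layers

  # Map pulse times onto steps (mass in g C cm^-2).
  pulse_mass <- numeric(H)
  if (!is.null(schedule) && schedule$total_input > 0) {
    idx <- floor(schedule$times / dt) + 1
    if (any(idx > H)) stop("pulse schedule extends beyond the forcing")
    for (i in idx) pulse_mass[i] <- pulse_mass[i] +
        g_m2_to_g_cm2(schedule$pulse_mass)
  }
  i_soc_rate <- g_m2_to_g_cm2(i_soc_total) / (n * H * dt)  # per layer, h^-1

  co2_h <- co2_g <- co2_m <- numeric(n)
  i_soc_cum <- i_doc_cum <- 0
  export <- influx <- 0
  hourly <- if (options$track_hourly)
    matrix(0, H, 5, dimnames = list(NULL, c("co2_hydrolysis", "co2_growth",
                                            "co2_maintenance", "doc_export",
                                            "doc_total"))) else NULL

  c0 <- total_carbon(state, column, forcing$M[1, ])
  kin <- tp$f < 1 && tp$alpha > 0 && tp$K_d > 0
  fkd <- tp$f * tp$K_d
  rho_b <- lay$rho_b
  # Conservative instantaneous re-equilibration of aqueous + type-1 mass;
  # theta_mass values the existing aqueous store, theta_new redistributes
  # (they differ only across a prescribed moisture change).
  equilibrate1 <- function(state, theta_mass, theta_new = theta_mass) {
    m1 <- (theta_mass * state$doc + rho_b * state$pdoc1) * dx
    state$doc <- m1 / ((theta_new + fkd * rho_b) * dx)
    state$pdoc1 <- fkd * state$doc
    state
  }
  theta_prev <- forcing$M[1, ]

  for (t in seq_len(H)) {
    theta <- forcing$M[t, ]
    Tt <- forcing$T[t, ]

    # Prescribed moisture change: added/removed water carries no DOC, so
    # the aqueous + type-1 mass is conserved while concentration adjusts.
    if (any(theta != theta_prev))
      state <- equilibrate1(state, theta_prev, theta)
    theta_prev <- theta

    if (pulse_mass[t] > 0) {
      state$doc <- apply_doc_pulse(state$doc, column, theta,
                                   pulse_mass[t])$doc
      state <- equilibrate1(state, theta)
      i_doc_cum <- i_doc_cum + pulse_mass[t]
    }

    if (!options$no_transport) {
      q <- water_flux(theta, column, bottom_bc = options$bottom_bc,
                      interface_mean = options$interface_mean)
      theta_face <- c(theta[1], (theta[-n] + theta[-1]) / 2, theta[n])
      v <- pore_water_velocity(q, theta_face)
      Ds <- dispersion_coefficient(v, tp)
      tr <- transport_step(state$doc, column, theta, q, Ds, tp, dt,
                           n_sub = options$n_sub_transport,
                           theta_t = options$theta_t)
      state$doc <- tr$doc
      state$pdoc1 <- tp$f * tp$K_d * state$doc
      export <- export + tr$export
      influx <- influx + tr$influx
    }

    if (kin) {
      sr <- sorption_step(state$doc, state$pdoc2, theta, lay$rho_b, tp,
                          dt, dx)
      state$doc <- sr$S_DOC
      state$pdoc1 <- sr$S_PDOC1
      state$pdoc2 <- sr$S_PDOC2
    }

    rx <- reaction_step(state, Tt, theta, rep(i_soc_rate, n), rp, dt,
                        theta = theta, dx = dx, tm = tm,
                        n_sub = options$n_sub_react)
    state <- rx$state
    state <- equilibrate1(state, theta)
    co2_h <- co2_h + rx$co2_hydrolysis
    co2_g <- co2_g + rx$co2_growth
    co2_m <- co2_m + rx$co2_maintenance
    i_soc_cum <- i_soc_cum + sum(rx$i_soc_applied)

    if (options$track_hourly)
      hourly[t, ] <- c(sum(rx$co2_hydrolysis), sum(rx$co2_growth),
                       sum(rx$co2_maintenance), export,
                       sum(forcing$M[t, ] * state$doc * dx))
  }

  # Type-1 re-equilibration after reactions moves mass between aqueous
  # and sorbed bookkeeping; account with the final theta.
  c1 <- total_carbon(state, column, forcing$M[H, ])
  inputs <- i_soc_cum + i_doc_cum + influx
  outputs <- sum(co2_h) + sum(co2_g) + sum(co2_m) + export
  residual <- (c1 - c0) - (inputs - outputs)
  rel_residual <- residual / max(inputs, c0, 1e-12)

  structure(list(state = state,
                 ledger = list(co2_hydrolysis = co2_h, co2_growth = co2_g,
                               co2_maintenance = co2_m,
                               doc_export = export, doc_influx = influx,
                               i_soc_applied = i_soc_cum,
                               i_doc_applied = i_doc_cum),
                 residual = rel_residual, hours = H * dt, dt = dt,
                 hourly = hourly,
                 column = column, schedule = schedule,
                 options = options),
            class = "season_run")
}

#' Spin the column up to equilibrium under mean forcing
#'
#' Repeats seasons of constant annual-mean forcing (no DOC pulses, SOC
#' input on) until the largest relative per-season change across the SOC,
#' DOC (aqueous + sorbed), and biomass totals drops below `tol`.
#'
#' @param state Starting `pool_state`.
#' @param column,archetype,rp,tp,tm As elsewhere.
#' @param mean_forcing Optional list(`T`, `M`) per-layer profiles;
#'   defaults to [forcing_annual_mean()].
#' @param options A [run_options()].
#' @param tol Relative per-season change tolerance.
#' @param max_seasons Abort (with diagnostics) beyond this many seasons.
#' @param dt Spin-up step (h); constant forcing permits long steps.
#' @param season_h Hours per spin-up season.
#' @return The equilibrated `pool_state`, with attributes
#'   `seasons_used` and `converged`.
#' @export
spinup <- function(state, column, archetype, rp = rate_params(),
                   tp = transport_params(), tm = tm_params(),
                   mean_forcing = NULL, options = run_options(),
                   tol = 1e-4, max_seasons = 400, dt = 6,
                   season_h = SEASON_HOURS) {
  if (is.null(mean_forcing))
    mean_forcing <- forcing_annual_mean(archetype, column)
  steps <- ceiling(season_h / dt)
  fc <- structure(list(
    time = (seq_len(steps) - 1) * dt,
    T = matrix(mean_forcing$T, steps, column$n_layers, byrow = TRUE),
    M = matrix(mean_forcing$M, steps, column$n_layers, byrow = TRUE),
    depth = column$layers$depth), class = "doc_forcing")
  pools <- function(s) c(soc = sum(s$soc),
                         doc = sum(s$doc) + sum(s$pdoc1) + sum(s$pdoc2),
                         mbc = sum(s$mbc))
  trace <- list()
  for (season in seq_len(max_seasons)) {
    before <- pools(state)
    run <- run_season(state, column, fc, schedule = NULL, rp = rp,
                      tp = tp, tm = tm, i_soc_total = archetype$i_soc,
                      options = options, dt = dt)
    state <- run$state
    after <- pools(state)
    rel <- abs(after - before) / pmax(abs(before), 1e-15)
    trace[[season]] <- rel
    if (max(rel) < tol) {
      attr(state, "seasons_used") <- season
      attr(state, "converged") <- TRUE
      return(state)
    }
  }
  stop("spin-up did not converge within ", max_seasons,
       " seasons; last relative changes: ",
       paste(signif(trace[[max_seasons]], 3), collapse = ", "))
}

#' Apply a uniform warming offset to forcing
#'
#' Adds `dT` to every temperature record; moisture is unchanged.
#'
#' @param forcing A `doc_forcing`.
#' @param dT Temperature offset (degC).
#' @return The shifted forcing.
#' @export
warming_experiment <- function(forcing, dT) {
  forcing$T <- forcing$T + dT
  forcing
}

#' Real priming effect from a paired treatment/baseline
#'
#' Real priming is the extra CO2 released from the SOC pool through
#' hydrolysis due to the introduced DOC: the difference in cumulative
#' hydrolysis CO2 between a pulsed run and its pulse-free baseline.
#' Growth and maintenance CO2 are excluded by construction (apparent
#' priming is out of scope).  Positive values are stimulation, negative
#' suppression.
#'
#' @param treatment,baseline `season_run` objects sharing column, forcing,
#'   and parameters; the baseline must have received no pulsed DOC.
#' @return Object of class `priming_result`: per-layer and total priming
#'   (g C m^-2 season^-1).
#' @export
compute_priming <- function(treatment, baseline) {
  if (treatment$column$n_layers != baseline$column$n_layers ||
      treatment$hours != baseline$hours)
    stop("treatment and baseline runs are not comparable")
  if (baseline$ledger$i_doc_applied != 0)
    stop("baseline run received pulsed DOC; priming undefined")
  per_layer <- g_cm2_to_g_m2(treatment$ledger$co2_hydrolysis -
                             baseline$ledger$co2_hydrolysis)
  structure(list(per_layer = per_layer, total = sum(per_layer),
                 depth = treatment$column$layers$depth,
                 treatment_co2 = g_cm2_to_g_m2(
                   sum(treatment$ledger$co2_hydrolysis) +
                   sum(treatment$ledger$co2_growth) +
                   sum(treatment$ledger$co2_maintenance)),
                 baseline_co2 = g_cm2_to_g_m2(
                   sum(baseline$ledger$co2_hydrolysis) +
                   sum(baseline$ledger$co2_growth) +
                   sum(baseline$ledger$co2_maintenance))),
            class = "priming_result")
}

#' Paired priming experiment
#'
#' Runs the treatment (pulsed DOC per `schedule`) and its pulse-free
#' baseline from the same initial state, forcing, and parameters, and
#' returns the priming plus both runs.
#'
#' @inheritParams run_season
#' @param archetype A [site_archetype()] supplying the SOC input rate.
#' @return List `priming`, `treatment`, `baseline`.
#' @export
prime_experiment <- function(state, column, forcing, schedule, archetype,
                             rp = rate_params(), tp = transport_params(),
                             tm = tm_params(), options = run_options()) {
  tr <- run_season(state, column, forcing, schedule, rp, tp, tm,
                   i_soc_total = archetype$i_soc, options = options)
  bl <- run_season(state, column, forcing, NULL, rp, tp, tm,
                   i_soc_total = archetype$i_soc, options = options)
  list(priming = compute_priming(tr, bl), treatment = tr, baseline = bl)
}

#' Priming over a grid of input fraction x pulse period x necromass
#' routing
#'
#' One paired (treatment, baseline) priming value per grid cell.  The
#' baseline depends only on `Y_B`, so it is computed once per `Y_B` value.
#' Per-cell failures are recorded and the grid continues.
#'
#' @param state Spun-up `pool_state` shared by all cells.
#' @param column,forcing,archetype,rp,tp,tm,options As elsewhere.
#' @param fractions DOC input fractions of annual NPP.
#' @param periods Pulse periods (h).
#' @param yb_values Values of the necromass-to-DOC fraction `Y_B`.
#' @return A data.frame (`fraction`, `period_h`, `y_b`, `priming`,
#'   `treatment_co2`, `baseline_co2`, `error`).
#' @export
experiment_grid <- function(state, column, forcing, archetype,
                            fractions = c(0.1, 0.3, 0.5),
                            periods = c(3, 30, 120, 360, 900, 1800),
                            yb_values = c(0, 0.5, 1),
                            rp = rate_params(), tp = transport_params(),
                            tm = tm_params(), options = run_options()) {
  cells <- expand.grid(fraction = fractions, period_h = periods,
                       y_b = yb_values, KEEP.OUT.ATTRS = FALSE)
  cells$priming <- NA_real_
  cells$treatment_co2 <- NA_real_
  cells$baseline_co2 <- NA_real_
  cells$error <- NA_character_
  baselines <- list()
  for (yb in yb_values) {
    rp_y <- rp; rp_y$Y_B <- yb
    baselines[[as.character(yb)]] <- tryCatch(
      run_season(state, column, forcing, NULL, rp_y, tp, tm,
                 i_soc_total = archetype$i_soc, options = options),
      error = function(e) e)
  }
  for (i in seq_len(nrow(cells))) {
    yb <- cells$y_b[i]
    bl <- baselines[[as.character(yb)]]
    if (inherits(bl, "error")) {
      cells$error[i] <- conditionMessage(bl)
      next
    }
    rp_y <- rp; rp_y$Y_B <- yb
    sched <- generate_pulse_schedule(archetype, cells$fraction[i],
                                     cells$period_h[i],
                                     season_h = nrow(forcing$T))
    res <- tryCatch({
      tr <- run_season(state, column, forcing, sched, rp_y, tp, tm,
                       i_soc_total = archetype$i_soc, options = options)
      compute_priming(tr, bl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      cells$error[i] <- conditionMessage(res)
    } else {
      cells$priming[i] <- res$total
      cells$treatment_co2[i] <- res$treatment_co2
      cells$baseline_co2[i] <- res$baseline_co2
    }
  }
  class(cells) <- c("priming_grid", class(cells))
  cells
}
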