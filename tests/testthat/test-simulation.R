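# Whole-model orchestration on a deliberately small setup: a short
# synthetic season on the WD column keeps these checks fast; the
# full-season properties live in the acceptance suite.

short_setup <- function(hours = 400, seed = 21) {
  arch <- site_archetype("WD")
  col <- generate_column(arch)
  list(arch = arch, col = col,
       fc = generate_forcing(arch, col, seed = seed, hours = hours))
}

test_that("state initialization applies the 3% biomass rule and the
           sorption fixed points", {
  col <- generate_column(site_archetype("WD"))
  tp <- transport_params(K_d = 2, f = 0.4)
  col$layers$soc0[3] <- 0
  st <- initialize_state(col, tp, doc0 = 4e-5)
  expect_equal(st$mbc, 0.03 * col$layers$soc0)
  expect_equal(st$mbc[3], 0)                       # no SOC, no microbes
  expect_equal(st$pdoc1, tp$f * tp$K_d * st$doc)
  expect_equal(st$pdoc2, (1 - tp$f) * tp$K_d * st$doc)
  # the kinetic fixed point carries zero initial exchange flux
  sr <- sorption_step(st$doc, st$pdoc2, rep(0.5, 10), col$layers$rho_b,
                      tp, dt = 10)
  expect_equal(sr$S_PDOC2, st$pdoc2, tolerance = 1e-12)
})

test_that("warming shifts every temperature and inverts exactly", {
  s <- short_setup(48)
  expect_identical(warming_experiment(s$fc, 0), s$fc)
  w <- warming_experiment(s$fc, 3)
  expect_equal(w$T, s$fc$T + 3)
  expect_identical(w$M, s$fc$M)
  expect_equal(warming_experiment(w, -3)$T, s$fc$T, tolerance = 1e-14)
})

test_that("a season closes its carbon ledger and is bit-reproducible", {
  s <- short_setup()
  st <- initialize_state(s$col)
  sched <- pulse_schedule(20, 60, season_h = 400)
  r1 <- run_season(st, s$col, s$fc, sched, i_soc_total = 20)
  r2 <- run_season(st, s$col, s$fc, sched, i_soc_total = 20)
  expect_lt(abs(r1$residual), 1e-10)
  expect_identical(r1$state, r2$state)             # paired determinism
  expect_identical(r1$ledger, r2$ledger)
  expect_gt(r1$ledger$i_doc_applied, 0)
})

test_that("an empty schedule equals no schedule at all", {
  s <- short_setup()
  st <- initialize_state(s$col)
  r0 <- run_season(st, s$col, s$fc, NULL, i_soc_total = 20)
  rz <- run_season(st, s$col, s$fc, pulse_schedule(0, 60, season_h = 400),
                   i_soc_total = 20)
  expect_equal(rz$state, r0$state)
  expect_equal(rz$ledger, r0$ledger)
})

test_that("with transport off, DOC moves only through reactions and
           pulses", {
  s <- short_setup()
  st <- initialize_state(s$col)
  opts <- run_options(no_transport = TRUE)
  r <- run_season(st, s$col, s$fc, pulse_schedule(10, 50, season_h = 400),
                  i_soc_total = 20, options = opts)
  expect_equal(r$ledger$doc_export, 0)
  expect_equal(r$ledger$doc_influx, 0)
  expect_lt(abs(r$residual), 1e-10)
})

test_that("priming of a run against itself is exactly zero", {
  s <- short_setup()
  st <- initialize_state(s$col)
  r <- run_season(st, s$col, s$fc, NULL, i_soc_total = 20)
  pr <- compute_priming(r, r)
  expect_identical(pr$per_layer, rep(0, s$col$n_layers))
  expect_identical(pr$total, 0)
})

test_that("priming refuses a pulsed baseline and mismatched runs", {
  s <- short_setup()
  st <- initialize_state(s$col)
  tr <- run_season(st, s$col, s$fc, pulse_schedule(10, 50, season_h = 400),
                   i_soc_total = 20)
  expect_error(compute_priming(tr, tr), "pulsed DOC")
})

test_that("priming on a zero-flow toy matches an independent fine-step
           integration", {
  # two layers, transport off, constant forcing: the coupled ODEs are
  # integrated independently with explicit Euler at dt = 0.02 h and the
  # hydrolysis-CO2 difference compared with the package's priming.
  col <- uniform_column(n = 2, dx = 1, rho_b = 0.08, soc = 0.01)
  rp <- rate_params(b_min_frac = 0, tau_act = 0)
  tp <- transport_params(K_d = 0, f = 0, alpha = 0)
  Tc <- 12; M <- 0.45
  hours <- 240
  fc <- structure(list(time = 0:(hours - 1),
                       T = matrix(Tc, hours, 2), M = matrix(M, hours, 2),
                       depth = col$layers$depth), class = "doc_forcing")
  st <- initialize_state(col, tp, doc0 = 2e-5)
  opts <- run_options(no_transport = TRUE, n_sub_react = 4)
  sched <- pulse_schedule(2, 24, season_h = hours)  # 2 g C m-2 in pulses
  tr <- run_season(st, col, fc, sched, rp, tp, i_soc_total = 1,
                   options = opts)
  bl <- run_season(st, col, fc, NULL, rp, tp, i_soc_total = 1,
                   options = opts)
  pkg_priming <- compute_priming(tr, bl)$total

  oracle <- function(pulsed) {
    dt <- 0.02
    F <- tm_scalar(Tc, M)
    soc <- st$soc; B <- st$mbc; m <- M * st$doc * col$dx
    i_rate <- g_m2_to_g_cm2(1) / (2 * hours)
    pulse_hours <- if (pulsed) seq(0, hours - 1e-9, by = 24) else numeric()
    pmass <- if (pulsed) g_m2_to_g_cm2(2) / length(pulse_hours) else 0
    co2h <- 0
    for (step in seq_len(hours / dt)) {
      t_now <- (step - 1) * dt
      if (pulsed && any(abs(t_now - pulse_hours) < dt / 2))
        m[1] <- m[1] + pmass
      g <- B / (B + rp$k_i * soc)
      H <- rp$k_OC * F * soc * g * rp$f_act * dt
      sat <- rp$c_half / (rp$c_half + m / M)
      U <- rp$k_DOC * F * rp$f_act * rp$k_i * g * sat * m * dt
      D <- rp$k_B * B * dt
      Mm <- rp$k_m * B * dt
      soc <- soc - H + (1 - rp$Y_B) * D + i_rate * dt
      m <- m + rp$Y_OC * H + rp$Y_B * D - U
      B <- B + rp$Y_DOC * U - D - Mm
      co2h <- co2h + sum((1 - rp$Y_OC) * H)
    }
    co2h
  }
  oracle_priming <- g_cm2_to_g_m2(oracle(TRUE) - oracle(FALSE))
  expect_equal(pkg_priming, oracle_priming,
               tolerance = 0.02 * abs(oracle_priming) /
                 max(abs(pkg_priming), 1e-12))
})

test_that("spin-up reaches a fixed point and is idempotent there", {
  # a compact column and short synthetic season keep this affordable
  arch <- site_archetype("WD", organic_thickness = 4)
  col <- generate_column(arch, thicknesses = c(
    dead_moss_slightly_decomposed = 1, moderately_decomposed = 2,
    well_decomposed = 1))
  sp <- spinup(initialize_state(col), col, arch, tol = 1e-4,
               max_seasons = 600, dt = 12, season_h = 1200)
  expect_true(attr(sp, "converged"))
  sp2 <- spinup(sp, col, arch, tol = 1e-4, max_seasons = 600, dt = 12,
                season_h = 1200)
  expect_equal(attr(sp2, "seasons_used"), 1)      # already at the point
  expect_equal(sum(sp2$soc), sum(sp$soc), tolerance = 2e-4)
})
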