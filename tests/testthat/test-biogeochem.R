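test_that("rate parameters convert day-based coefficients once", {
  rp <- rate_params()
  expect_equal(rp$k_OC, 0.019 / 24)
  expect_equal(rp$k_DOC, 6590 / 24)
  expect_equal(rp$k_m, 0.01 / 24)
  expect_equal(rp$k_B, 0.0002)          # already hourly
  conv <- attr(rp, "conversions")
  expect_equal(conv$stored_per_hour, conv$input_per_day / 24)
  expect_error(rate_params(Y_DOC = 1.2), "\\[0, 1\\]")
})

test_that("F(T, M) matches hand-evaluated points, is nonnegative and
           deterministic", {
  # frozen hand evaluations of 2^((T-20)/10) * 4(M-0.01)(1-M)/0.99^2
  expect_equal(tm_scalar(5, 0.4), 0.337645111310381, tolerance = 1e-14)
  expect_equal(tm_scalar(12, 0.3), 0.475840763318841, tolerance = 1e-14)
  grid <- expand.grid(T = seq(-20, 25, length.out = 12),
                      M = seq(0.01, 0.95, length.out = 12))
  F1 <- tm_scalar(grid$T, grid$M)
  expect_true(all(F1 >= 0))
  expect_identical(F1, tm_scalar(grid$T, grid$M))
  expect_error(tm_scalar(NA, 0.3), "non-finite")
})

test_that("hydrolysis needs microbes and conserves what it splits", {
  rp <- rate_params()
  expect_equal(hydrolysis_fluxes(1, 0, 1, rp, 1)$soc_loss, 0)
  h1 <- hydrolysis_fluxes(0.5, 0.01, 0.8, rate_params(Y_OC = 1), 1)
  expect_equal(h1$co2, 0)
  expect_equal(h1$doc_gain, h1$soc_loss)
  set.seed(1)
  S <- runif(20); B <- runif(20) * 0.05; F <- runif(20, 0, 2)
  h <- hydrolysis_fluxes(S, B, F, rp, 2)
  expect_equal(h$doc_gain + h$co2, h$soc_loss, tolerance = 1e-15)
  expect_true(all(h$soc_loss <= S))
})

test_that("uptake conserves, vanishes without substrate, and saturates", {
  rp <- rate_params()
  expect_equal(uptake_fluxes(0, 0.01, 1, 1, rp, 1)$doc_loss, 0)
  u1 <- uptake_fluxes(1e-4, 0.01, 1, 1, rate_params(Y_DOC = 1), 1)
  expect_equal(u1$co2, 0)
  set.seed(2)
  m <- runif(20) * 1e-3; B <- runif(20) * 0.05; S <- runif(20)
  u <- uptake_fluxes(m, B, S, 0.7, rp, 1, conc = m / 0.4)
  expect_equal(u$biomass_gain + u$co2, u$doc_loss, tolerance = 1e-15)
  expect_true(all(u$doc_loss <= m))
  # Michaelis-Menten: at concentrations far above c_half the specific
  # uptake drops toward zero
  lo <- uptake_fluxes(1e-6, 0.01, 1, 1, rp, 1, conc = 1e-7)$doc_loss / 1e-6
  hi <- uptake_fluxes(1e-2, 0.01, 1, 1, rp, 1, conc = 1e-2 / 0.4)$doc_loss / 1e-2
  expect_gt(lo, 10 * hi)
})

test_that("death splits necromass by Y_B and conserves it", {
  d0 <- death_fluxes(0.01, rate_params(Y_B = 0), 1)
  expect_equal(d0$doc_gain, 0)
  expect_equal(d0$soc_gain, d0$biomass_loss)
  d5 <- death_fluxes(0.01, rate_params(Y_B = 0.5), 1)
  expect_equal(d5$doc_gain, d5$soc_gain)
  set.seed(3)
  B <- runif(10) * 0.1
  d <- death_fluxes(B, rate_params(Y_B = 0.3), 4)
  expect_equal(d$doc_gain + d$soc_gain, d$biomass_loss, tolerance = 1e-15)
})

test_that("maintenance is linear in biomass and blind to climate", {
  rp <- rate_params()
  expect_equal(maintenance_flux(0, rp, 1), 0)
  expect_equal(maintenance_flux(0.02, rp, 1), 2 * maintenance_flux(0.01, rp, 1))
  # identical at -5 and +15 degC by construction: co2 = k_m * B * dt
  expect_equal(maintenance_flux(0.01, rp, 1), rp$k_m * 0.01)
})

test_that("a reaction step with all rates zero is the identity", {
  col <- uniform_column(n = 4, dx = 1)
  rp <- rate_params(k_OC = 0, k_DOC = 0, k_B = 0, k_m = 0,
                    b_min_frac = 0, tau_act = 0)
  st <- initialize_state(col, transport_params(), doc0 = 2e-5)
  out <- reaction_step(st, rep(5, 4), rep(0.4, 4), rep(0, 4), rp, 1,
                       theta = rep(0.4, 4))
  expect_equal(out$state$soc, st$soc)
  expect_equal(out$state$mbc, st$mbc)
  expect_equal(out$state$doc, st$doc, tolerance = 1e-15)
  expect_equal(sum(out$co2_hydrolysis + out$co2_growth +
                     out$co2_maintenance), 0)
})

test_that("random reaction steps close the per-layer carbon balance", {
  set.seed(11)
  col <- uniform_column(n = 8, dx = 1)
  theta <- runif(8, 0.3, 0.6)
  for (rep_i in 1:5) {
    rp <- rate_params(Y_B = runif(1), Y_OC = runif(1), Y_DOC = runif(1, 0.1, 1))
    st <- initialize_state(col, transport_params(), doc0 = runif(1) * 1e-4)
    st$mbc <- runif(8) * 0.01
    before <- sum(st$soc + st$mbc) + sum(theta * st$doc)
    out <- reaction_step(st, runif(8, -5, 20), theta, rep(1e-7, 8), rp,
                         dt = 1, theta = theta, n_sub = 2)
    after <- sum(out$state$soc + out$state$mbc) + sum(theta * out$state$doc)
    flux <- sum(out$i_soc_applied) -
      sum(out$co2_hydrolysis + out$co2_growth + out$co2_maintenance)
    expect_equal(after - before, flux, tolerance = 1e-10 * max(before, 1))
  }
})

test_that("a supply balancing growth against losses holds biomass
           stationary", {
  # single layer, no hydrolysis, necromass recycled to DOC so SOC is
  # inert; solve the discrete balance for the external DOC supply that
  # makes growth exactly offset death + maintenance, then integrate
  # 1000 h and check stationarity.
  col <- uniform_column(n = 1, dx = 1)
  theta <- 0.5
  rp <- rate_params(k_OC = 0, Y_B = 1, b_min_frac = 0, tau_act = 0)
  S <- 0.02; B0 <- 5e-4
  lr <- rp$k_B + rp$k_m
  loss <- B0 * (1 - exp(-lr))          # per 1-h step
  U_need <- loss / rp$Y_DOC
  D_death <- loss * rp$k_B / lr
  i_doc <- U_need - rp$Y_B * D_death   # external supply per step
  # stationary aqueous mass: U = m (1 - exp(-u sat(m))) = U_need
  g <- B0 / (B0 + rp$k_i * S)
  u <- rp$k_DOC * 1 * rp$f_act * rp$k_i * g   # F = 1 at reference T, M
  m_star <- uniroot(function(m) {
    sat <- rp$c_half / (rp$c_half + m / theta)
    m * (1 - exp(-u * sat)) - U_need
  }, c(1e-12, 1), tol = 1e-14)$root

  # the step consumes U from (m_start + recycled necromass), so the
  # stationary start-of-step mass is m_star - Y_B * D
  st <- initialize_state(col, transport_params(), doc0 = 0)
  st$soc <- S; st$mbc <- B0
  st$doc <- (m_star - rp$Y_B * D_death) / theta
  Tref <- 20; Mopt <- 0.505             # F(Tref, Mopt) = 1 exactly
  B_traj <- numeric(1000)
  for (h in 1:1000) {
    out <- reaction_step(st, Tref, Mopt, 0, rp, 1, theta = theta)
    st <- out$state
    st$doc <- st$doc + i_doc / theta    # external drip refills the pool
    B_traj[h] <- st$mbc
  }
  expect_lt(max(abs(B_traj - B0)) / B0, 1e-3)
})
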