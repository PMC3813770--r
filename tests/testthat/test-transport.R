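test_that("dispersion closure is linear in |v| plus diffusion", {
  tp <- transport_params(D_w = 0.1, dispersivity = 2)
  expect_equal(dispersion_coefficient(0, tp), 0.1)
  expect_equal(dispersion_coefficient(1.5, tp), 3.1)
  expect_equal(dispersion_coefficient(-1.5, tp), 3.1)
})

test_that("transport without advection or dispersion is the identity", {
  col <- uniform_column(n = 20, dx = 1)
  doc <- runif(20)
  st <- transport_step(doc, col, rep(0.4, 20), rep(0, 21), rep(0, 21),
                       transport_params(D_w = 0), dt = 5)
  expect_identical(st$doc, doc)
  expect_equal(st$export, 0)
  expect_equal(st$influx, 0)
})

test_that("column mass change equals net boundary flux exactly", {
  set.seed(7)
  col <- uniform_column(n = 30, dx = 1)
  tp <- transport_params(K_d = 2, f = 0.4)
  theta <- runif(30, 0.3, 0.6)
  q <- rep(0.2, 31)
  Ds <- rep(0.5, 31)
  doc <- runif(30) * 1e-4
  beta <- theta + tp$f * tp$K_d * col$layers$rho_b
  for (tt in c(0.5, 1)) {
    st <- transport_step(doc, col, theta, q, Ds, tp, dt = 2, theta_t = tt)
    dm <- sum(beta * st$doc) - sum(beta * doc)
    expect_equal(dm, st$influx - st$export, tolerance = 1e-12)
  }
})

test_that("tracer run matches the closed-form advection-dispersion
           solution on a refined grid", {
  v <- 1; D <- 0.5; theta <- 0.3; Tend <- 30
  col <- uniform_column(n = 300, dx = 0.25)
  tp <- transport_params(D_w = 0, dispersivity = 0, K_d = 0, f = 0,
                         alpha = 0)
  out <- run_tracer(col, rep(0, 300), theta, q = v * theta, D = D, tp,
                    hours = Tend, dt = 0.25)
  exact <- ade_closed_form(col$layers$depth, Tend, v, D)
  err <- sqrt(sum((out$doc - exact)^2) / sum(exact^2))
  expect_lt(err, 0.01)
})

test_that("two-site sorption conserves carbon and honors its limits", {
  theta <- 0.45; rho_b <- 0.1; dx <- 1
  tp <- transport_params(K_d = 3, f = 0.4, alpha = 0.3)
  total <- function(c, s2, f, K_d)
    (theta + f * K_d * rho_b) * c * dx + rho_b * s2 * dx
  c0 <- 2e-4; s20 <- 1e-4
  st <- sorption_step(c0, s20, theta, rho_b, tp, dt = 1.5, dx = dx)
  expect_equal(total(st$S_DOC, st$S_PDOC2, tp$f, tp$K_d),
               total(c0, s20, tp$f, tp$K_d), tolerance = 1e-12)
  expect_equal(st$S_PDOC1, tp$f * tp$K_d * st$S_DOC)

  # fixed point: type-2 already at its target => nothing moves
  s2_eq <- (1 - tp$f) * tp$K_d * c0
  st2 <- sorption_step(c0, s2_eq, theta, rho_b, tp, dt = 10, dx = dx)
  expect_equal(st2$S_DOC, c0, tolerance = 1e-12)
  expect_equal(st2$S_PDOC2, s2_eq, tolerance = 1e-12)

  # frozen kinetics
  tp0 <- transport_params(K_d = 3, f = 0.4, alpha = 0)
  st3 <- sorption_step(c0, s20, theta, rho_b, tp0, dt = 10, dx = dx)
  expect_identical(st3$S_PDOC2, s20)

  # pure equilibrium (f = 1): all sorbed mass sits on type-1 sites
  tp1 <- transport_params(K_d = 3, f = 1, alpha = 0.3)
  st4 <- sorption_step(c0, 0, theta, rho_b, tp1, dt = 5, dx = dx)
  expect_equal(st4$S_PDOC1, tp1$K_d * st4$S_DOC)
  expect_equal(st4$S_PDOC2, 0)
})

test_that("kinetic relaxation follows its exact exponential law", {
  theta <- 0.5; rho_b <- 0.08; dx <- 1
  tp <- transport_params(K_d = 2, f = 0.3, alpha = 0.4)
  c0 <- 1e-4; s20 <- 5e-5
  dt <- 2.5
  # independent closed form of the two-pool linear exchange
  beta <- theta + tp$f * tp$K_d * rho_b
  kd2 <- (1 - tp$f) * tp$K_d
  mt <- beta * c0 * dx + rho_b * s20 * dx
  A <- kd2 * mt / (beta * dx)
  Bc <- 1 + kd2 * rho_b / beta
  s2_expect <- A / Bc + (s20 - A / Bc) * exp(-tp$alpha * Bc * dt)
  st <- sorption_step(c0, s20, theta, rho_b, tp, dt, dx)
  expect_equal(st$S_PDOC2, s2_expect, tolerance = 1e-14)
})

test_that("pulses add exactly their mass to the surface layer", {
  col <- uniform_column(n = 5, dx = 1)
  theta <- rep(0.4, 5)
  doc <- rep(1e-5, 5)
  expect_identical(apply_doc_pulse(doc, col, theta, 0)$doc, doc)
  m <- 3e-4
  st <- apply_doc_pulse(doc, col, theta, m)
  expect_equal(st$doc[1] - doc[1], m / (theta[1] * col$dx))
  expect_equal(st$doc[-1], doc[-1])
  # additivity: two half pulses equal one full pulse
  two <- apply_doc_pulse(apply_doc_pulse(doc, col, theta, m / 2)$doc,
                         col, theta, m / 2)$doc
  expect_equal(two, st$doc, tolerance = 1e-15)
  expect_error(apply_doc_pulse(doc, col, theta, -1), "nonnegative")
})

test_that("zero-inlet transport conserves mass plus cumulative export", {
  col <- uniform_column(n = 40, dx = 0.5)
  tp <- transport_params(K_d = 0.5, f = 0.5, alpha = 0)
  theta <- rep(0.4, 40)
  beta <- theta + tp$f * tp$K_d * col$layers$rho_b
  doc <- c(rep(2e-4, 10), rep(0, 30))
  m0 <- sum(beta * doc * col$dx)
  export <- 0
  for (s in 1:60) {
    st <- transport_step(doc, col, theta, rep(0.3, 41), rep(0.2, 41),
                         tp, dt = 1)
    doc <- st$doc
    export <- export + st$export
  }
  expect_gt(export, 0)
  expect_equal(sum(beta * doc * col$dx) + export, m0, tolerance = 1e-12)
})

test_that("refining the sub-step leaves the solution nearly unchanged", {
  col <- uniform_column(n = 50, dx = 0.5)
  tp <- transport_params()
  theta <- rep(0.45, 50)
  doc <- exp(-((col$layers$depth - 5) / 2)^2) * 1e-4
  run <- function(n_sub) {
    d <- doc
    for (s in 1:20)
      d <- transport_step(d, col, theta, rep(0.25, 51), rep(0.3, 51), tp,
                          dt = 1, n_sub = n_sub,
                          advection = "upwind")$doc
    d
  }
  d1 <- run(8); d2 <- run(16)
  expect_lt(sqrt(sum((d1 - d2)^2) / sum(d2^2)), 0.01)
})
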