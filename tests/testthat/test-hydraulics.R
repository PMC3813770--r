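vg_moss <- vg_params(K_sat = 1017.4, theta_r = 0.04, theta_s = 0.95,
                     n = 2.38)
vg_dead <- vg_params(K_sat = 100.8, theta_r = 0.01, theta_s = 0.93,
                     n = 1.9)

test_that("effective saturation hits its endpoints and midpoint", {
  expect_equal(effective_saturation(0.95, vg_moss), 1)
  expect_equal(effective_saturation(0.04, vg_moss), 0)
  expect_equal(effective_saturation((0.04 + 0.95) / 2, vg_moss), 0.5)
  expect_warning(se <- effective_saturation(0.99, vg_moss), "clamped")
  expect_equal(se, 1)
  expect_error(vg_params(1, 0.5, 0.5, 2), "degenerate")
})

test_that("conductivity matches the closed form and is monotone", {
  expect_equal(hydraulic_conductivity(0.95, vg_moss), 1017.4)
  expect_equal(hydraulic_conductivity(0.04, vg_moss), 0)
  # frozen hand evaluation at Se = 0.5: m = 1 - 1/2.38,
  # K = 1017.4 * 0.5^0.5 * (1 - (1 - 0.5^(1/m))^m)^2
  expect_equal(hydraulic_conductivity(0.495, vg_moss), 25.5792432557365,
               tolerance = 1e-12)
  th <- seq(0.05, 0.95, length.out = 200)
  expect_true(all(diff(hydraulic_conductivity(th, vg_moss)) >= 0))
})

test_that("matric potential inverts the retention curve", {
  expect_equal(matric_potential(0.95, vg_moss), 0)
  # frozen hand evaluation: h = -(1/0.1) * (0.5^(-1/m) - 1)^(1/2.38)
  expect_equal(matric_potential(0.495, vg_moss), -14.2030122032536,
               tolerance = 1e-12)
  th <- seq(0.05, 0.949, length.out = 100)
  h <- matric_potential(th, vg_moss)
  expect_true(all(diff(h) > 0))                 # strictly monotone
  expect_equal(retention_moisture(h, vg_moss), th, tolerance = 1e-10)
  expect_error(matric_potential(0.04, vg_moss), "undefined")
})

test_that("uniform moisture drains by gravity and residual soil is dry", {
  col <- uniform_column(n = 10, dx = 1, K_sat = 100.8, theta_r = 0.01,
                        theta_s = 0.93, vg_n = 1.9)
  th <- rep(0.4, 10)
  J <- water_flux(th, col)
  K <- hydraulic_conductivity(0.4, vg_dead)
  expect_equal(J[2:10], rep(K, 9), tolerance = 1e-12)
  J0 <- water_flux(rep(0.01, 10), col)
  expect_equal(max(abs(J0)), 0, tolerance = 1e-10)
})

test_that("a hydrostatic head profile carries no interior flux", {
  col <- uniform_column(n = 20, dx = 1, K_sat = 100.8, theta_r = 0.01,
                        theta_s = 0.93, vg_n = 1.9)
  # h = x - L: unit head gradient exactly cancels gravity
  h <- col$layers$depth - col$L
  th <- retention_moisture(h, vg_dead)
  J <- water_flux(th, col)
  expect_equal(J[2:20], rep(0, 19), tolerance = 1e-10)
})

test_that("a two-layer moisture step reproduces the hand-computed flux", {
  col <- uniform_column(n = 2, dx = 1, K_sat = 100.8, theta_r = 0.01,
                        theta_s = 0.93, vg_n = 1.9)
  J <- water_flux(c(0.3, 0.5), col)
  # frozen hand evaluation: K1 = K(0.3), K2 = K(0.5),
  # J = sqrt(K1 K2) * (1 - (h(0.5) - h(0.3)) / dx) -- capillarity pulls
  # water upward against gravity here, hence the negative sign.
  expect_equal(J[2], -6.01649867105959, tolerance = 1e-10)
})

test_that("pore-water velocity divides flux by moisture with a dry floor", {
  expect_equal(pore_water_velocity(0, 0.25), 0)
  expect_equal(pore_water_velocity(0.5, 0.25), 2)
  expect_warning(v <- pore_water_velocity(0.1, 1e-6), "capped")
  expect_equal(v, 0.1 / 1e-3)
})

test_that("steady drainage profile yields uniform interface fluxes", {
  arch <- site_archetype("WD")
  col <- generate_column(arch)
  th <- steady_moisture_profile(col, 0.005)
  J <- water_flux(th, col)
  expect_equal(J[2:(col$n_layers + 1)], rep(0.005, col$n_layers),
               tolerance = 1e-6)
  expect_equal(hydraulic_conductivity(
    moisture_at_flux(0.005, vg_dead), vg_dead), 0.005, tolerance = 1e-9)
})

test_that("saturated layers over an impermeable base are stagnant", {
  col <- uniform_column(n = 6, dx = 1, K_sat = 0.036, theta_r = 0.22,
                        theta_s = 0.83, vg_n = 1.6)
  th <- c(0.5, 0.6, 0.83, 0.83, 0.83, 0.83)
  J <- water_flux(th, col, bottom_bc = "impermeable")
  expect_equal(J[4:7], rep(0, 4))
  expect_gt(abs(J[2]), 0)
})
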