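loam <- soil_catalogue("loam")
sand <- soil_catalogue("sand")
clay <- soil_catalogue("clay")

test_that("retention curve reproduces the benchmark soil anchors", {
  expect_equal(water_content(0, sand), 0.43)
  expect_equal(water_content(0, loam), 0.43)
  expect_equal(water_content(0, clay), 0.40)
  # the drying-scenario anchor: theta at -659.8 cm in loam
  expect_equal(round(water_content(-659.8, loam), 3), 0.129)
  # deep dry limit approaches residual (the approach rate scales with n:
  # sand converges fast; clay with n = 1.1 only logarithmically)
  expect_lt(abs(water_content(-1e8, sand) - sand$theta_res), 1e-6)
  expect_gt(water_content(-1e8, clay), water_content(-1e30, clay))
  expect_lt(abs(water_content(-1e300, clay) - clay$theta_res), 1e-6)
})

test_that("invalid soil parameters are rejected", {
  expect_error(vg_soil(0.5, 0.4, 0.04, 1.6, 50), "theta_res")
  expect_error(vg_soil(0.08, 0.43, -1, 1.6, 50), "alpha")
  expect_error(vg_soil(0.08, 0.43, 0.04, 0.9, 50), "n must")
  expect_error(soil_catalogue("peat"), "unknown soil")
})

test_that("inverse retention curve is exact and round-trips", {
  expect_equal(pressure_head(loam$theta_sat, loam), 0)
  # the printed 0.129 is theta(-659.8) rounded; the exact inverse of the
  # unrounded value recovers the head
  th <- water_content(-659.8, loam)
  expect_lt(abs(pressure_head(th, loam) - (-659.8)), 1e-8)
  set.seed(7)
  for (soil in list(sand, loam, clay)) {
    th <- runif(100, soil$theta_res + 1e-4, soil$theta_sat)
    expect_lt(max(abs(water_content(pressure_head(th, soil), soil) - th)),
              1e-10)
  }
  expect_error(pressure_head(loam$theta_res, loam), "outside")
})

test_that("conductivity matches the Mualem form and its limits", {
  expect_equal(hydraulic_conductivity(loam$theta_sat, loam), 50)
  expect_equal(hydraulic_conductivity(loam$theta_res, loam), 0)
  # independent hand evaluation at mid saturation for sand
  th <- (sand$theta_res + sand$theta_sat) / 2
  se <- 0.5
  m <- 1 - 1 / 3
  k_hand <- 1000 * se^0.5 * (1 - (1 - se^(1 / m))^m)^2
  expect_equal(hydraulic_conductivity(th, sand), k_hand, tolerance = 1e-12)
})

test_that("retention and conductivity are monotone over the full range", {
  for (soil in list(sand, loam, clay)) {
    psi <- -10^seq(-2, 6, length.out = 300)
    th <- water_content(psi, soil)
    expect_true(all(diff(th) <= 1e-15))          # drier head, less water
    thg <- seq(soil$theta_res, soil$theta_sat, length.out = 300)
    expect_true(all(diff(hydraulic_conductivity(thg, soil)) >= -1e-15))
  }
})

test_that("diffusivity equals K * dpsi/dtheta (finite-difference oracle)", {
  for (soil in list(sand, loam, clay)) {
    th <- seq(soil$theta_res + 0.02, soil$theta_sat - 0.02,
              length.out = 20)
    dw <- water_diffusivity(th, soil)
    psi <- pressure_head(th, soil)
    dp <- 1e-5 * pmax(abs(psi), 1)
    dth_dpsi <- (water_content(psi + dp, soil) -
                   water_content(psi - dp, soil)) / (2 * dp)
    fd <- hydraulic_conductivity(th, soil) / dth_dpsi
    expect_lt(max(abs(dw - fd) / fd), 1e-4)
  }
  # linearity in K_sat
  loam2 <- vg_soil(0.08, 0.43, 0.04, 1.6, 100, 0.5)
  expect_equal(water_diffusivity(0.2, loam2),
               2 * water_diffusivity(0.2, loam))
  expect_error(water_diffusivity(loam$theta_sat, loam), "strictly inside")
})

test_that("diffusivity is monotone increasing for sand away from limits", {
  th <- seq(sand$theta_res + 0.01, sand$theta_sat - 0.01,
            length.out = 100)
  expect_true(all(diff(water_diffusivity(th, sand)) > 0))
})

test_that("matric flux potential: limits, additivity, quadrature oracle", {
  expect_equal(matric_flux_potential(-15000, loam), 0)
  a <- matric_flux_potential(-100, loam)
  b <- matric_flux_potential(-1000, loam)
  ab <- a - b    # integral from -1000 to -100
  # additivity
  expect_lt(abs((matric_flux_potential(-100, loam, -1000)) - ab), 1e-6)
  # brute-force composite trapezoid on a dense grid
  h <- seq(-15000, -100, length.out = 2e5)
  brute <- sum(diff(h) * (conductivity_psi(h[-1], loam) +
                            conductivity_psi(h[-length(h)], loam)) / 2)
  expect_lt(abs(a - brute) / brute, 1e-3)
  # strict monotonicity and inversion
  psis <- c(-12000, -5000, -800, -50)
  phis <- matric_flux_potential(psis, loam)
  expect_true(all(diff(phis) > 0))
  expect_lt(max(abs(invert_mfp(phis, loam) - psis) / abs(psis)), 1e-5)
})

test_that("MPa/head conversion matches the wilting-point anchor", {
  expect_lt(abs(mpa_to_head(-1.5) - (-15290)), 10)
  expect_equal(head_to_mpa(mpa_to_head(-0.3)), -0.3, tolerance = 1e-12)
})

test_that("compiled kernel hydraulics agree with the R implementations", {
  # the 1D solver carries its own van Genuchten evaluation; pin them
  # against each other through a solver equilibrium: a hydrostatic state
  # must be an exact fixed point for every soil
  for (soil in list(sand, loam, clay)) {
    g <- soil_grid_vertical(50, 25)
    st <- soil_state(g, soil, function(z) -120 - z)
    res <- richards_step(st, g, soil,
                         list(top = bc_no_flux(), bottom = bc_no_flux()),
                         0.01)
    expect_true(res$converged)
    expect_lt(max(abs(res$state$psi - st$psi)), 1e-8)
  }
})
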