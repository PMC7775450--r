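p_t24 <- binding_params(xi0 = 4.2, c_star = 2.6e11, b_max = 100,
                        slope_high = 6.6e-11 * 4.2)

test_that("available site fraction interpolates from 1/xi0 to 1", {
  f0 <- available_site_fraction(1e6, p_t24)      # far below c*
  expect_equal(f0, 1 / 4.2, tolerance = 1e-6)
  expect_equal(available_site_fraction(0, p_t24), 1 / 4.2, tolerance = 1e-6)
  # sub-critical charge density: no condensation at any dose
  p_low <- binding_params(0.9, 2.6e11, 100, 17e-11)
  expect_equal(available_site_fraction(c(0, 1e10, 1e13), p_low), rep(1, 3))
  # logistic midpoint: xi_eff at c* is the geometric mean of (xi0, 1)
  expect_equal(available_site_fraction(2.6e11, p_t24), 1 / sqrt(4.2),
               tolerance = 1e-12)
  # monotone in c, decreasing in xi0
  cc <- 10^seq(9, 13, length.out = 50)
  expect_true(all(diff(available_site_fraction(cc, p_t24)) >= 0))
  p_hi <- binding_params(6, 2.6e11, 100, 1e-10)
  expect_true(all(available_site_fraction(cc, p_hi) <=
                    available_site_fraction(cc, p_t24) + 1e-12))
  expect_error(available_site_fraction(-1, p_t24), "non-negative")
})

test_that("binding mean agrees with the brute-force Euler accumulation", {
  doses <- nine_doses()
  bm <- binding_mean(doses, p_t24)
  oracle <- vapply(doses, euler_binding_mean, numeric(1), params = p_t24)
  expect_true(all(abs(bm - oracle) / oracle < 1e-3))
  # noiseless curve is non-decreasing and saturates at b_max
  expect_true(all(diff(bm) > 0))
  expect_equal(binding_mean(1e15, p_t24), 100, tolerance = 1e-4)
  expect_equal(binding_mean(0, p_t24), 0)
})

test_that("linear and saturating limits of the simulated curve", {
  # xi0 <= 1 and doses far below saturation: B ~ slope * c
  p_lin <- binding_params(0.9, 2.6e11, 100, 17e-11)
  doses <- c(1e9, 5e9, 1e10)
  cur <- simulate_binding_curve(p_lin, doses, noise_cv = 0)
  expect_equal(cur$signal, 17e-11 * doses, tolerance = 1e-2)
  # reproducibility for a fixed seed
  c1 <- simulate_binding_curve(p_t24, nine_doses(), 0.05, 4, seed = 11)
  c2 <- simulate_binding_curve(p_t24, nine_doses(), 0.05, 4, seed = 11)
  expect_identical(c1, c2)
  expect_error(simulate_binding_curve(p_t24, numeric(0)), "empty")
})

test_that("normalization scales the maximum to exactly 100 and is idempotent", {
  cur <- dose_binding_curve(c(1, 2, 3), c(2, 4, 8))
  nc <- normalize_curve(cur)
  expect_equal(nc$signal, c(25, 50, 100))
  expect_identical(normalize_curve(nc)$signal, nc$signal)
  big <- dose_binding_curve(c(1, 2, 3), c(1.1e4, 2.0e4, 3.7e4))
  nb <- normalize_curve(big)
  expect_equal(max(nb$signal), 100)
  expect_equal(nb$signal / nb$signal[3], big$signal / big$signal[3])
  expect_error(normalize_curve(dose_binding_curve(1:3, c(0, 0, 0))),
               "positive")
})

test_that("initial slope recovers a noiseless linear increment exactly", {
  doses <- c(1e10, 2e10, 3e10, 6e10)
  cur <- dose_binding_curve(doses, 17e-11 * doses)
  sl <- initial_slope(cur)
  expect_equal(sl$slope, 17e-11, tolerance = 1e-12)
  zero <- dose_binding_curve(doses, rep(0, 4))
  expect_equal(initial_slope(zero)$slope, 0)
  # two generators with slope ratio 17.0/6.6 yield that fitted ratio
  cur2 <- dose_binding_curve(doses, 6.6e-11 * doses)
  expect_equal(initial_slope(cur)$slope / initial_slope(cur2)$slope,
               17.0 / 6.6, tolerance = 1e-10)
})

test_that("cooperativity index separates condensation regimes", {
  doses <- nine_doses()
  ci <- cooperativity_index(simulate_binding_curve(p_t24, doses, 0))
  expect_equal(ci$ratio, 4.2, tolerance = 0.15)
  expect_true(ci$cooperative)
  # linear (non-cooperative) curve: ratio ~ 1
  lin <- dose_binding_curve(doses / 100, 17e-11 * doses / 100)
  expect_equal(cooperativity_index(lin)$ratio, 1, tolerance = 0.05)
  # condensation disabled: attenuated, ratio ~ 1
  sf <- gen_binding_dataset("salt_free", doses = doses, noise_cv = 0,
                            n_replicates = 1)
  ci_sf <- cooperativity_index(sf)
  expect_equal(ci_sf$ratio, 1, tolerance = 0.1)
  expect_false(ci_sf$cooperative)
})

test_that("chain length estimate is linear in c* and inverse in geometry", {
  geo <- chain_geometry(charges_per_particle = 4e4, cells_per_ml = 6.7e5,
                        chains_per_cell = 1e7, charges_per_nm = 4)
  l1 <- estimate_chain_length(2.6e11, geo)
  l2 <- estimate_chain_length(1.2e11, geo)
  expect_equal(l1 / l2, 2.6 / 1.2, tolerance = 1e-12)
  geo2 <- chain_geometry(4e4, 6.7e5, 2e7, 4)
  expect_equal(estimate_chain_length(2.6e11, geo2), l1 / 2)
  # unit scaling: geometry with unit conversion factor returns c* itself
  geo1 <- chain_geometry(1, 1, 1, 1)
  expect_equal(estimate_chain_length(42, geo1), 42)
  expect_error(chain_geometry(0, 1, 1), "positive")
})
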