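test_that("Hill model respects its analytic identities", {
  p <- hill_params(0.2, 6, 2.5)
  expect_equal(hill_vacuole_model(0, p), 0)
  # half-maximum at k_half for any exponent
  for (n in c(0.7, 1, 2.5, 7))
    expect_equal(hill_vacuole_model(6, hill_params(0.2, 6, n)), 0.1)
  expect_equal(hill_vacuole_model(2, hill_params(1, 1, 1)), 2 / 3)
  tt <- seq(0, 30, by = 0.1)
  expect_true(all(diff(hill_vacuole_model(tt, p)) >= 0))
  expect_lt(abs(hill_vacuole_model(1e6, p) - 0.2), 1e-6)
  expect_error(hill_vacuole_model(-1, p), "non-negative")
})

test_that("noiseless Hill samples are recovered to optimizer tolerance", {
  tt <- seq(0, 10, by = 1 / 12)    # 5-min sampling over 10 h
  truth <- hill_params(0.2, 6, 2.5)
  tc <- vacuole_timecourse(tt, hill_vacuole_model(tt, truth))
  fit <- fit_vacuole_kinetics(tc)
  expect_true(fit$converged)
  expect_equal(fit$params$nv_max, 0.2, tolerance = 1e-5)
  expect_equal(fit$params$k_half, 6, tolerance = 1e-5)
  expect_equal(fit$params$n_hill, 2.5, tolerance = 1e-4)
  expect_equal(fit$k_inv * fit$params$k_half, 1)
})

test_that("flat series and the zero-dose scenario do not converge", {
  tt <- seq(0, 10, by = 0.5)
  expect_false(fit_vacuole_kinetics(
    vacuole_timecourse(tt, rep(0, length(tt))))$converged)
  z <- gen_vacuole_timecourse("t24", dose_uM = 125, seed = 1)
  expect_false(fit_vacuole_kinetics(z[[1]])$converged)
  expect_false(fit_vacuole_kinetics(average_timecourses(z))$converged)
})

test_that("k_inv recovery is accurate and order-preserving under noise", {
  ks <- vapply(1:10, function(s) {
    tcs <- gen_vacuole_timecourse("t24", seed = s)
    fit_vacuole_kinetics(average_timecourses(tcs))$k_inv
  }, numeric(1))
  expect_equal(median(ks), 1 / 5, tolerance = 0.1)
  # doubled half-time halves the deposition-ability metric
  ks2 <- vapply(1:10, function(s) {
    tcs <- gen_vacuole_timecourse("custom",
                                  params = hill_params(0.2, 10, 2.5),
                                  seed = 100 + s)
    fit_vacuole_kinetics(average_timecourses(tcs))$k_inv
  }, numeric(1))
  expect_equal(median(ks) / median(ks2), 2, tolerance = 0.1)
})
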