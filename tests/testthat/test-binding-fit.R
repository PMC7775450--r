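test_that("noiseless self-consistency: generating parameters are recovered", {
  p <- binding_params(4.2, 2.6e11, 100, 6.6e-11 * 4.2)
  cur <- normalize_curve(simulate_binding_curve(p, nine_doses(), 0))
  fit <- fit_condensation_model(cur)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["xi0"]), 4.2, tolerance = 1e-4)
  expect_equal(unname(fit$estimates["c_star"]), 2.6e11, tolerance = 1e-4)
  # predictions reproduce the data
  expect_lt(max(abs(residuals(fit))), 1e-4)
})

test_that("noisy recovery: median xi0 and c* over seeds stay near truth", {
  res <- t(vapply(1:8, function(s) {
    cur <- gen_binding_dataset("t24_control", seed = s)
    f <- fit_condensation_model(normalize_curve(cur))
    c(f$estimates["xi0"], f$estimates["c_star"], f$converged)
  }, numeric(3)))
  expect_true(all(res[, 3] == 1))
  expect_equal(median(res[, 1]), 4.2, tolerance = 0.15)
  expect_equal(median(res[, 2]), 2.6e11, tolerance = 0.2)
})

test_that("single-regime curves are flagged unidentifiable", {
  p <- binding_params(4.2, 2.6e11, 100, 6.6e-11 * 4.2)
  narrow <- simulate_binding_curve(p, c(1e11, 1.5e11, 2e11, 2.5e11), 0)
  expect_warning(fit <- fit_condensation_model(narrow), "single dose regime")
  expect_false(fit$converged)
  expect_false(fit$identifiable)
})

test_that("fit methods expose coefficients, predictions and simulation", {
  p <- binding_params(4.2, 2.6e11, 100, 6.6e-11 * 4.2)
  cur <- normalize_curve(simulate_binding_curve(p, nine_doses(), 0.05, 4,
                                                seed = 3))
  fit <- fit_condensation_model(cur)
  expect_named(coef(fit), c("xi0", "c_star", "b_max", "slope_high"))
  expect_length(predict(fit, c(1e11, 5e11)), 2)
  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_s3_class(sim, "dose_binding_curve")
  expect_equal(nrow(sim), 2 * length(nine_doses()))
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("converged", out)))
})
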