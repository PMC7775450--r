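test_that("generators are deterministic for a fixed seed", {
  expect_identical(gen_binding_dataset("t24_control", seed = 5),
                   gen_binding_dataset("t24_control", seed = 5))
  expect_identical(gen_impedance_trace("t24", seed = 5),
                   gen_impedance_trace("t24", seed = 5))
  expect_identical(gen_vacuole_timecourse("t24", seed = 5),
                   gen_vacuole_timecourse("t24", seed = 5))
  i1 <- gen_cluster_image(22, seed = 5); i2 <- gen_cluster_image(22, seed = 5)
  expect_identical(as.vector(i1), as.vector(i2))
  s1 <- gen_motility_stack(n_frames = 3, seed = 5)
  s2 <- gen_motility_stack(n_frames = 3, seed = 5)
  expect_identical(s1$frames, s2$frames)
})

test_that("binding presets reproduce the reference model behaviour", {
  # strong condensation: cooperativity index near xi0 = 4.2
  cur <- gen_binding_dataset("t24_control", noise_cv = 0, n_replicates = 1)
  expect_equal(cooperativity_index(cur)$ratio, 4.2, tolerance = 0.15)
  # no condensation: near-linear low-dose region at the reference slope
  uro <- gen_binding_dataset("urotsa", doses = c(1e10, 2e10, 3e10),
                             noise_cv = 0, n_replicates = 1)
  expect_equal(initial_slope(uro)$slope, 17.0e-11, tolerance = 0.03)
})

test_that("noiseless impedance traces peak at 30 min and then follow the model", {
  raw <- gen_impedance_trace("t24", noise_sd = 0, seed = 1)
  tr <- normalize_impedance(raw$time_h, raw$impedance_ohm,
                            attr(raw, "treatment_time"))
  t_pk <- tr$time_h[which.max(tr$value)]
  expect_equal(t_pk, 0.5, tolerance = 1e-9)
  post <- tr[tr$time_h >= 0.5, ]
  expect_equal(post$value,
               impedance_model(post$time_h - 0.5, attr(raw, "truth")),
               tolerance = 1e-9)
})

test_that("vacuole time-courses start at zero and scale with dose", {
  tcs <- gen_vacuole_timecourse("t24", seed = 2)
  for (tc in tcs) expect_equal(tc$value[1], 0)
  t500 <- attr(gen_vacuole_timecourse("t24", dose_uM = 500, seed = 2),
               "truth")
  t250 <- attr(gen_vacuole_timecourse("t24", dose_uM = 250, seed = 2),
               "truth")
  expect_equal(t500$nv_max / t250$nv_max, 2)
  expect_equal(attr(gen_vacuole_timecourse("t24", dose_uM = 125,
                                           seed = 2), "truth")$nv_max, 0)
})

test_that("cluster images realize the target density and Poisson NN spacing", {
  dens <- vapply(1:20, function(s)
    attr(gen_cluster_image(22, field_um = 3, seed = s), "true_density"),
    numeric(1))
  expect_equal(mean(dens), 22, tolerance = 0.1)
  expect_equal(nrow(attr(gen_cluster_image(0, seed = 1), "coordinates")), 0L)
  # mean nearest-neighbour distance of a Poisson process: 0.5/sqrt(lambda)
  nn_mean <- mean(vapply(1:15, function(s) {
    xy <- as.matrix(attr(gen_cluster_image(22, field_um = 3, seed = s),
                         "coordinates"))
    d <- as.matrix(dist(xy)); diag(d) <- Inf
    mean(apply(d, 1, min))
  }, numeric(1)))
  expect_equal(nn_mean, 0.5 / sqrt(22) * 1000, tolerance = 0.08)
})
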