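test_that("both thresholds separate a perfectly bimodal image", {
  img <- matrix(c(rep(10, 40), rep(200, 24)), 8, 8)
  for (m in c("mean_dark", "triangle_dark")) {
    mask <- auto_threshold(img, m)
    expect_identical(unname(as.vector(mask)), as.vector(img == 200))
  }
  expect_error(auto_threshold(matrix(7, 4, 4)), "degenerate")
})

test_that("mean threshold of a uniform-random image is near the intensity mean", {
  set.seed(42)
  img <- matrix(sample(0:255, 10000, replace = TRUE), 100, 100)
  mask <- auto_threshold(img, "mean_dark")
  expect_lt(abs(attr(mask, "threshold") - mean(img)), 1)
})

test_that("triangle threshold matches the exhaustive-search oracle", {
  # delta peak at 20 plus a skewed tail to 250
  set.seed(7)
  h <- integer(256)
  h[21] <- 5000
  tail_vals <- 21:250
  h[tail_vals + 1L] <- round(400 * exp(-(tail_vals - 20) / 60))
  img_vals <- rep(0:255, times = h)
  img_vals <- img_vals[sample.int(length(img_vals))]
  n_use <- 64 * (length(img_vals) %/% 64)
  img <- matrix(img_vals[seq_len(n_use)], nrow = 64)
  mask <- auto_threshold(img, "triangle_dark")
  thr <- attr(mask, "threshold")
  expect_identical(thr, triangle_threshold_oracle(glycobind:::.hist256(img)))
  expect_gt(thr, 20)     # strictly between the mode ...
  expect_lt(thr, 250)    # ... and the tail end
  # agreement with the oracle on random histograms
  for (s in 1:10) {
    set.seed(s)
    img <- matrix(pmin(255, rpois(4096, sample(5:50, 1)) +
                         sample(0:150, 4096, replace = TRUE,
                                prob = exp(-(0:150) / 30))), 64, 64)
    expect_identical(attr(auto_threshold(img, "triangle_dark"), "threshold"),
                     triangle_threshold_oracle(glycobind:::.hist256(img)))
  }
})

test_that("triangle masks are invariant to an intensity shift", {
  set.seed(11)
  img <- matrix(pmin(200, rpois(4096, 15) +
                       sample(c(rep(0, 9), 120), 4096, replace = TRUE)), 64, 64)
  m1 <- auto_threshold(img, "triangle_dark")
  m2 <- auto_threshold(img + 40, "triangle_dark")
  expect_identical(as.vector(m1), as.vector(m2))
})

test_that("motility index is zero for static stacks and exact on 4x4 alternation", {
  # identical frames throughout
  frame <- matrix(c(rep(0, 8), rep(200, 8)), 4, 4)
  st <- image_stack(replicate(5, frame, simplify = FALSE), pixel_size = 1)
  expect_equal(motility_index(st)$index_series, rep(0, 4))
  # alternating all-0 / all-1 binary 4x4 frames: population SD of {0,1}
  # per pixel is 0.5, brute-force over the 16 pixels
  a <- matrix(0, 4, 4); b <- matrix(1, 4, 4)
  st2 <- image_stack(list(a, b, a, b), pixel_size = 1)
  mi <- motility_index(st2)
  brute <- mean(vapply(1:16, function(i) sd(c(0, 1)) * sqrt(1 / 2),
                       numeric(1)))   # population SD = sample SD * sqrt((n-1)/n)
  expect_equal(mi$index_series, rep(brute, 3))
  expect_equal(mi$index_series, rep(0.5, 3))
  expect_error(motility_index(image_stack(list(a), pixel_size = 1)),
               "2 frames")
})

test_that("stronger jitter yields a higher motility index", {
  m <- vapply(c(1, 2), function(sig) {
    mean(vapply(1:5, function(s) {
      st <- gen_motility_stack(n_frames = 8, jitter_sigma = sig, seed = s)
      mean(motility_index(st)$index_series)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(m[2], m[1])
  # sigma = 0 gives exactly zero
  st0 <- gen_motility_stack(n_frames = 5, jitter_sigma = 0, seed = 1)
  expect_equal(motility_index(st0)$index_series, rep(0, 4))
})

test_that("vacuole area of a rendered disk matches the analytic area", {
  size <- 128
  xg <- matrix(seq_len(size) - 0.5, size, size, byrow = TRUE)
  yg <- matrix(seq_len(size) - 0.5, size, size)
  r_px <- 14
  img <- matrix(10, size, size)
  img[(xg - 64)^2 + (yg - 64)^2 <= r_px^2] <- 220
  st <- image_stack(list(matrix(10, size, size), img), pixel_size = 0.5,
                    frame_interval = 1)
  tc <- vacuole_area_fraction(st, n_cells = 1)
  expect_equal(tc$value[1], 0)
  expect_equal(tc$value[2], pi * (r_px * 0.5)^2, tolerance = 0.03)
  expect_error(vacuole_area_fraction(st, n_cells = 0), ">= 1")
})

test_that("a Hill-scheduled vacuole stack yields a recoverable half-time", {
  truth <- hill_params(60, 5, 2.5)    # total area in um^2 over time
  st <- gen_motility_stack(n_frames = 120, size = 128, n_blobs = 0,
                           vacuole = truth, n_vacuoles = 4,
                           pixel_size = 0.5, frame_interval = 1 / 12,
                           seed = 3)
  tc <- vacuole_area_fraction(st, n_cells = 1)
  fit <- fit_vacuole_kinetics(tc)
  expect_true(fit$converged)
  expect_equal(fit$params$k_half, 5, tolerance = 0.15)
})

test_that("cluster detection is exact on well-separated spots and empty fields", {
  img0 <- matrix(2, 100, 100)
  sg <- (60 / 2.3548) / 20
  centers <- seq(10, 90, by = 20)
  for (cx in centers) for (cy in centers)
    for (i in -6:6) for (j in -6:6)
      img0[cy + i, cx + j] <- img0[cy + i, cx + j] +
        150 * exp(-(i^2 + j^2) / (2 * sg^2))
  r <- detect_clusters(img0, pixel_size = 20)
  expect_equal(r$n_clusters, 25L)
  expect_equal(r$density, 25 / 4)    # 25 spots in a 2x2 um field
  expect_equal(r$mean_spacing, 400, tolerance = 0.01)  # 20 px grid
  expect_equal(detect_clusters(matrix(3, 50, 50), 20)$n_clusters, 0L)
})

test_that("cluster density is recovered across the biological range", {
  for (d in c(5, 30)) {
    dens <- vapply(1:8, function(s)
      detect_clusters(gen_cluster_image(d, seed = s), 20)$density,
      numeric(1))
    expect_equal(median(dens), d, tolerance = 0.15)
  }
})
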