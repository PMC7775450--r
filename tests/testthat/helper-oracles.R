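# Independent oracles used across test files.

# Brute-force Euler accumulation of the binding mean model:
# dB = slope_high * f(c) * (1 - B/b_max) * dc on a fine uniform grid.
euler_binding_mean <- function(cmax, params, n = 100000L) {
  cs <- seq(0, cmax, length.out = n)
  dc <- cs[2] - cs[1]
  f <- available_site_fraction(cs, params)
  B <- 0
  for (i in 2:n) B <- B + params$slope_high * f[i] * (1 - B / params$b_max) * dc
  B
}

# Exhaustive-search triangle threshold: maximize the distance between
# the histogram and the peak-to-tail-end line over all 256 candidate
# levels (mirrored when the longer tail is on the left).
triangle_threshold_oracle <- function(h) {
  nz <- which(h > 0)
  lo <- min(nz) - 1L; hi <- max(nz) - 1L
  peak <- which.max(h) - 1L
  flip <- (peak - lo) > (hi - peak)
  if (flip) {
    h <- rev(h); peak <- 255L - peak; hi <- 255L - lo
  }
  best <- peak; best_d <- -Inf
  hpeak <- h[peak + 1L]
  if (hi > peak) {
    for (i in (peak + 1L):hi) {
      d <- (hi - peak) * (hpeak - h[i + 1L]) - hpeak * (i - peak)
      if (d > best_d) { best_d <- d; best <- i }
    }
  }
  if (flip) 255L - best else best
}

# Nine-dose grid used by the condensation binding experiments.
nine_doses <- function() dose_grid("nine_dose")
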