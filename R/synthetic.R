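## Scenario presets.  Reference model values: xi0 = 4.2 (control T24) /
## 1.5 (heparinase), c* = 2.6e11 / 1.2e11 particles/mL, low-dose observed
## slopes 17.0e-11 (UROtsa) / 6.6e-11 (T24) %·mL·particle^-1.  The model's
## observed low-dose slope is slope_high/xi0, so the T24 intrinsic slope
## is 6.6e-11 * 4.2.
.binding_scenarios <- function() {
  t24_slope_high <- 6.6e-11 * 4.2
  list(
    t24_control = binding_params(xi0 = 4.2, c_star = 2.6e11,
                                 b_max = 100, slope_high = t24_slope_high),
    t24_heparinase = binding_params(xi0 = 1.5, c_star = 1.2e11,
                                    b_max = 100, slope_high = t24_slope_high),
    urotsa = binding_params(xi0 = 0.9, c_star = 2.6e11,
                            b_max = 100, slope_high = 17.0e-11),
    salt_free = binding_params(xi0 = 1, c_star = 2.6e11,
                               b_max = 100, slope_high = t24_slope_high)
  )
}

## Assay dose grids: the nine-dose grid of the condensation
## experiment and the five-dose grid of the normalized comparison.
#' Standard dose grids
#'
#' The two particle-concentration grids used by the binding assays: the
#' nine-dose grid (`"nine_dose"`, 4.97e10 ... 1.27e12 particles/mL) on
#' which the condensation model is fitted, and the five-dose grid
#' (`"five_dose"`, 1.12e11 ... 1.78e12) of the normalized cell-line
#' comparison.
#'
#' @param which `"nine_dose"` or `"five_dose"`.
#' @return Numeric vector of concentrations in particles/mL.
#' @export
dose_grid <- function(which = c("nine_dose", "five_dose")) {
  which <- match.arg(which)
  switch(which,
         nine_dose = c(4.97e10, 7.46e10, 1.12e11, 1.68e11, 2.52e11,
                       3.78e11, 5.66e11, 8.48e11, 1.27e12),
         five_dose = c(1.12e11, 2.24e11, 4.48e11, 8.96e11, 1.78e12))
}

#' Generate a synthetic dose-binding dataset
#'
#' Replicate dose-binding curves from a named scenario preset (or custom
#' parameters) via [simulate_binding_curve()].  Scenarios:
#' `"t24_control"` (strong condensation, xi0 = 4.2, c* = 2.6e11),
#' `"t24_heparinase"` (weak condensation, xi0 = 1.5, c* = 1.2e11),
#' `"urotsa"` (no condensation, xi0 < 1, steep low-dose slope) and
#' `"salt_free"` (condensation disabled).  Output is byte-identical for
#' a fixed seed.
#'
#' @param scenario Scenario name, or `"custom"` with `params` supplied.
#' @param doses Dose grid (particles/mL); default: nine-dose grid for
#'   the T24 scenarios, five-dose grid otherwise.
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param n_replicates Replicates per dose (default 4).
#' @param seed Integer seed.
#' @param params A [binding_params()] for `scenario = "custom"`.
#' @return A [dose_binding_curve()] labelled with the scenario.
#' @examples
#' gen_binding_dataset("t24_control", seed = 1)
#' @export
gen_binding_dataset <- function(scenario = c("t24_control", "t24_heparinase",
                                             "urotsa", "salt_free", "custom"),
                                doses = NULL, noise_cv = 0.05,
                                n_replicates = 4L, seed = NULL,
                                params = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "custom") {
    if (!inherits(params, "binding_params"))
      stop("scenario 'custom' requires 'params'")
  } else {
    params <- .binding_scenarios()[[scenario]]
  }
  if (is.null(doses)) {
    doses <- if (scenario %in% c("t24_control", "t24_heparinase"))
      dose_grid("nine_dose") else dose_grid("five_dose")
  }
  simulate_binding_curve(params, doses, noise_cv = noise_cv,
                         n_replicates = n_replicates, seed = seed,
                         condition = scenario)
}

## ECIS ground-truth presets: a-ratio 2 between the cell lines encodes
## the stronger particle binding of the cancer line.
.ecis_scenarios <- function() list(
  t24 = ecis_params(z0 = 1, z_max = 0.35, a = 1.5,
                    hill = hill_params(0.25, 6, 3)),
  urotsa = ecis_params(z0 = 1, z_max = 0.18, a = 3,
                       hill = hill_params(0.12, 10, 3)),
  no_vacuole = ecis_params(z0 = 1, z_max = 0.35, a = 1.5,
                           hill = hill_params(0, 6, 3))
)

#' Generate a synthetic raw ECIS trace
#'
#' Raw impedance series (ohms) with a pre-treatment baseline, a rise to
#' a peak about 30 min after treatment (smooth half-cosine ramp, so the
#' noiseless post-peak segment exactly follows the impedance model with
#' time referenced to the peak), the exponential binding decay and the
#' vacuole term, plus additive Gaussian noise.  5-min sampling over 24 h
#' post-treatment by default.
#'
#' @param scenario `"t24"`, `"urotsa"`, `"no_vacuole"` or `"custom"`.
#' @param params An [ecis_params()] for `scenario = "custom"`.
#' @param baseline_ohm Absolute pre-treatment impedance (default 900).
#' @param treatment_time Treatment time on the raw clock, hours
#'   (default 2: a 2-h baseline precedes it).
#' @param duration Post-treatment duration in hours (default 24).
#' @param dt Sampling interval in hours (default 1/12, i.e. 5 min).
#' @param t_peak Rise time to the binding peak in hours (default 0.5).
#' @param noise_sd Additive noise SD on the normalized scale
#'   (default 0.02).
#' @param seed Integer seed.
#' @param frequency Metadata frequency in Hz (default 4000).
#' @return A `data.frame` with columns `time_h` (raw clock) and
#'   `impedance_ohm`, with the ground-truth [ecis_params()] attached as
#'   attribute `"truth"` and `t_peak`, `treatment_time`, `frequency` as
#'   attributes.
#' @export
gen_impedance_trace <- function(scenario = c("t24", "urotsa", "no_vacuole",
                                             "custom"),
                                params = NULL, baseline_ohm = 900,
                                treatment_time = 2, duration = 24,
                                dt = 1 / 12, t_peak = 0.5,
                                noise_sd = 0.02, seed = NULL,
                                frequency = 4000) {
  scenario <- match.arg(scenario)
  if (scenario == "custom") {
    if (!inherits(params, "ecis_params"))
      stop("scenario 'custom' requires 'params'")
  } else {
    params <- .ecis_scenarios()[[scenario]]
  }
  if (!is.null(seed)) set.seed(seed)
  t_raw <- seq(0, treatment_time + duration, by = dt)
  t_rel <- t_raw - treatment_time
  m <- numeric(length(t_rel))
  pre <- t_rel < 0
  m[pre] <- params$z0
  rise <- t_rel >= 0 & t_rel < t_peak
  ramp <- (1 - cos(pi * t_rel[rise] / t_peak)) / 2
  m[rise] <- params$z0 + params$z_max * ramp
  post <- t_rel >= t_peak
  m[post] <- impedance_model(t_rel[post] - t_peak, params)
  vals <- m
  if (noise_sd > 0) vals <- vals + rnorm(length(vals), 0, noise_sd)
  out <- data.frame(time_h = t_raw, impedance_ohm = vals * baseline_ohm)
  attr(out, "truth") <- params
  attr(out, "t_peak") <- t_peak
  attr(out, "treatment_time") <- treatment_time
  attr(out, "frequency") <- frequency
  out
}

## vacuole-formation ground truth; the dose scaling mirrors the
## dose-dependent vacuole counts (none resolvable at the lowest dose)
.vacuole_scenarios <- function() list(
  t24 = hill_params(0.2, 5, 2.5),
  urotsa = hill_params(0.12, 10, 2.5)
)

#' Generate synthetic vacuole time-courses
#'
#' Replicate Hill-model time-courses with multiplicative log-normal
#' noise, sampled every 5 min over 10 h by default.  `nv_max` scales
#' with the capsaicin dose: 0 at 125 uM (no vacuole formation — fits on
#' that scenario must report non-convergence), the preset value at
#' 250 uM, and twice it at 500 uM.
#'
#' @param scenario `"t24"`, `"urotsa"` or `"custom"`.
#' @param params A [hill_params()] for `scenario = "custom"` (taken as
#'   the 250 uM value).
#' @param dose_uM Capsaicin dose label: 125, 250 (default) or 500.
#' @param duration Duration in hours (default 10).
#' @param dt Sampling interval in hours (default 1/12).
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param n_replicates Number of replicate series (default 3).
#' @param seed Integer seed.
#' @return A list of [vacuole_timecourse()] objects (one per
#'   replicate), with the ground-truth [hill_params()] attached as
#'   attribute `"truth"`.
#' @export
gen_vacuole_timecourse <- function(scenario = c("t24", "urotsa", "custom"),
                                   params = NULL, dose_uM = 250,
                                   duration = 10, dt = 1 / 12,
                                   noise_cv = 0.05, n_replicates = 3L,
                                   seed = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "custom") {
    if (!inherits(params, "hill_params"))
      stop("scenario 'custom' requires 'params'")
  } else {
    params <- .vacuole_scenarios()[[scenario]]
  }
  scale <- switch(as.character(dose_uM),
                  "125" = 0, "250" = 1, "500" = 2,
                  stop("'dose_uM' must be 125, 250 or 500"))
  eff <- if (scale > 0)
    hill_params(params$nv_max * scale, params$k_half, params$n_hill)
  else NULL
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration, by = dt)
  mu <- if (is.null(eff)) rep(0, length(tt)) else hill_vacuole_model(tt, eff)
  sdlog <- sqrt(log(1 + noise_cv^2))
  lab <- sprintf("%s_%duM", scenario, dose_uM)
  out <- lapply(seq_len(n_replicates), function(r) {
    v <- if (noise_cv > 0)
      mu * exp(rnorm(length(mu), -sdlog^2 / 2, sdlog)) else mu
    vacuole_timecourse(tt, v, condition = lab)
  })
  attr(out, "truth") <- if (is.null(eff)) hill_params(0, params$k_half,
                                                      params$n_hill) else eff
  out
}

#' Average replicate time-courses
#'
#' Pointwise mean of replicate [vacuole_timecourse()] series sharing a
#' time grid, for fitting a single consensus curve.
#'
#' @param tcs A list of [vacuole_timecourse()] objects.
#' @return A single [vacuole_timecourse()].
#' @export
average_timecourses <- function(tcs) {
  stopifnot(length(tcs) >= 1L,
            all(vapply(tcs, inherits, logical(1), "vacuole_timecourse")))
  t0 <- tcs[[1]]$time_h
  for (tc in tcs) if (!isTRUE(all.equal(tc$time_h, t0)))
    stop("replicate series must share a time grid")
  vals <- rowMeans(vapply(tcs, function(tc) tc$value,
                          numeric(length(t0))))
  vacuole_timecourse(t0, vals, condition = tcs[[1]]$condition[1])
}

#' Generate a synthetic STED-like cluster image
#'
#' Homogeneous Poisson point process of glycan clusters at a target
#' density, rendered with a Gaussian point-spread function and Poisson
#' shot noise on a constant background, at STED-like sampling (20 nm
#' pixels, 60 nm FWHM by default).
#'
#' @param density Target cluster density per square micrometre
#'   (default 22, the bladder-cancer-line value).
#' @param field_um Side length of the square field in micrometres
#'   (default 2, i.e. a 4 um^2 field).
#' @param pixel_size Pixel size in nm (default 20).
#' @param fwhm PSF full width at half maximum in nm (default 60).
#' @param peak_photons Expected peak photon count per spot
#'   (default 150).
#' @param background Expected background photons per pixel (default 3).
#' @param seed Integer seed.
#' @return A numeric photon-count matrix with attributes
#'   `"coordinates"` (true centres, nm), `"pixel_size"`, `"fwhm"` and
#'   `"true_density"` (realized point density per um^2).
#' @export
gen_cluster_image <- function(density = 22, field_um = 2, pixel_size = 20,
                              fwhm = 60, peak_photons = 150,
                              background = 3, seed = NULL) {
  if (density < 0) stop("'density' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  npx <- round(field_um * 1000 / pixel_size)
  area <- field_um^2
  n <- rpois(1, density * area)
  img_mu <- matrix(background, npx, npx)
  xs <- runif(n, 0, npx); ys <- runif(n, 0, npx)
  sigma_px <- (fwhm / 2.3548) / pixel_size
  if (n > 0) {
    r <- ceiling(4 * sigma_px)
    for (i in seq_len(n)) {
      cx <- xs[i]; cy <- ys[i]
      c0 <- max(1L, floor(cx - r)); c1 <- min(npx, ceiling(cx + r))
      r0 <- max(1L, floor(cy - r)); r1 <- min(npx, ceiling(cy + r))
      if (c1 < c0 || r1 < r0) next
      gx <- exp(-((c0:c1) - 0.5 - cx)^2 / (2 * sigma_px^2))
      gy <- exp(-((r0:r1) - 0.5 - cy)^2 / (2 * sigma_px^2))
      img_mu[r0:r1, c0:c1] <- img_mu[r0:r1, c0:c1] +
        peak_photons * outer(gy, gx)
    }
  }
  img <- matrix(rpois(length(img_mu), img_mu), npx, npx)
  attr(img, "coordinates") <- data.frame(x_nm = xs * pixel_size,
                                         y_nm = ys * pixel_size)
  attr(img, "pixel_size") <- pixel_size
  attr(img, "fwhm") <- fwhm
  attr(img, "true_density") <- n / area
  img
}

#' Generate a synthetic live-cell stack
#'
#' Time-lapse frames containing textured cell blobs with per-frame
#' Gaussian positional jitter (configurable per-frame sigma profile,
#' emulating changes of layer motility) and, optionally, bright vacuole
#' disks whose total area grows according to a Hill schedule.
#'
#' @param n_frames Number of frames (default 20).
#' @param size Frame side in pixels (default 96).
#' @param n_blobs Number of cell blobs (default 5; 0 for a pure vacuole
#'   stack).
#' @param jitter_sigma Per-frame jitter SD in pixels; scalar or length
#'   `n_frames` profile (default 0).
#' @param vacuole Optional [hill_params()]: total vacuole area in um^2
#'   per frame follows `hill_vacuole_model` at the frame times.
#' @param n_vacuoles Number of vacuole disks sharing that area
#'   (default 4).
#' @param pixel_size Pixel size in micrometres (default 0.5).
#' @param frame_interval Hours between frames (default 1/12).
#' @param seed Integer seed.
#' @return An [image_stack()] (channel `"fluorescence"` when `vacuole`
#'   is given, else `"phase_contrast"`).
#' @export
gen_motility_stack <- function(n_frames = 20L, size = 96L, n_blobs = 5L,
                               jitter_sigma = 0, vacuole = NULL,
                               n_vacuoles = 4L, pixel_size = 0.5,
                               frame_interval = 1 / 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sig <- rep_len(jitter_sigma, n_frames)
  blob_r <- size / 10
  cx <- runif(n_blobs, size * 0.2, size * 0.8)
  cy <- runif(n_blobs, size * 0.2, size * 0.8)
  amp <- runif(n_blobs, 150, 220)
  vx <- runif(n_vacuoles, size * 0.25, size * 0.75)
  vy <- runif(n_vacuoles, size * 0.25, size * 0.75)
  xg <- matrix(seq_len(size) - 0.5, size, size, byrow = TRUE)
  yg <- matrix(seq_len(size) - 0.5, size, size)
  tt <- seq(0, by = frame_interval, length.out = n_frames)
  frames <- array(0, dim = c(size, size, n_frames))
  for (f in seq_len(n_frames)) {
    img <- matrix(10, size, size)
    if (n_blobs > 0) {
      jx <- rnorm(n_blobs, 0, sig[f]); jy <- rnorm(n_blobs, 0, sig[f])
      for (b in seq_len(n_blobs)) {
        r2 <- (xg - (cx[b] + jx[b]))^2 + (yg - (cy[b] + jy[b]))^2
        img <- img + amp[b] * exp(-r2 / (2 * blob_r^2))
      }
    }
    if (!is.null(vacuole)) {
      a_um2 <- hill_vacuole_model(tt[f], vacuole)
      if (a_um2 > 0) {
        r_px <- sqrt(a_um2 / (n_vacuoles * pi)) / pixel_size
        for (v in seq_len(n_vacuoles)) {
          r2 <- (xg - vx[v])^2 + (yg - vy[v])^2
          img[r2 <= r_px^2] <- 230
        }
      }
    }
    frames[, , f] <- pmin(img, 255)
  }
  image_stack(frames, pixel_size = pixel_size,
              frame_interval = frame_interval,
              channel = if (is.null(vacuole)) "phase_contrast"
                        else "fluorescence")
}
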