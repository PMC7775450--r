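#' Parameters of the condensation-gated binding model
#'
#' Parameter set for the cooperative nanocapsule-binding model.  Below a
#' critical particle concentration `c_star`, counterion condensation on
#' the glycan chains screens binding sites: the available-site fraction
#' is `1/xi0`.  Around `c_star` the condensed counterions are released
#' (logistic transition in log10 concentration of width
#' `transition_width` decades) and the available-site fraction rises to
#' 1.  Bound signal accumulates with intrinsic slope `slope_high` per
#' available site and saturates at `b_max`.
#'
#' @param xi0 Initial dimensionless line charge density before any
#'   particle binding (> 0).  Values <= 1 mean no condensation: the
#'   available-site fraction is identically 1.
#' @param c_star Critical particle concentration in particles/mL (> 0).
#' @param b_max Saturation binding signal, in % of the normalized
#'   maximum (> 0; default 100).
#' @param slope_high Intrinsic binding increment in the uncondensed
#'   regime, in % per (particles/mL) (> 0).
#' @param transition_width Width of the condensation-release transition
#'   in decades of concentration (> 0; default 0.15).
#'
#' @return An object of class `binding_params`.
#' @examples
#' binding_params(xi0 = 4.2, c_star = 2.6e11, slope_high = 2.772e-10)
#' @export
binding_params <- function(xi0, c_star, b_max = 100, slope_high,
                           transition_width = 0.15) {
  stopifnot(is.numeric(xi0), length(xi0) == 1L, is.finite(xi0), xi0 > 0,
            is.numeric(c_star), length(c_star) == 1L, c_star > 0,
            is.numeric(b_max), length(b_max) == 1L, b_max > 0,
            is.numeric(slope_high), length(slope_high) == 1L, slope_high > 0,
            is.numeric(transition_width), transition_width > 0)
  structure(list(xi0 = xi0, c_star = c_star, b_max = b_max,
                 slope_high = slope_high,
                 transition_width = transition_width),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat("Condensation binding model parameters\n")
  cat(sprintf("  xi0:              %.4g\n", x$xi0))
  cat(sprintf("  c*:               %.4g particles/mL\n", x$c_star))
  cat(sprintf("  b_max:            %.4g %%\n", x$b_max))
  cat(sprintf("  slope_high:       %.4g %% per particle/mL\n", x$slope_high))
  cat(sprintf("  transition width: %.4g decades\n", x$transition_width))
  invisible(x)
}

#' Available binding-site fraction
#'
#' Fraction of glycan binding sites available to nanocapsules at
#' particle concentration `c`: `f(c) = 1/xi_eff(c)`, where the effective
#' line charge density `xi_eff` interpolates geometrically from `xi0`
#' far below the critical concentration to 1 far above it, via a
#' logistic in log10(c) centered at `c_star`.  Non-decreasing in `c`;
#' identically 1 when `xi0 <= 1` (no condensation).
#'
#' @param c Particle concentrations in particles/mL (>= 0; vectorized).
#' @param params A [binding_params()] object.
#' @return Available-site fractions in `(0, 1]`.
#' @examples
#' p <- binding_params(4.2, 2.6e11, slope_high = 2.772e-10)
#' available_site_fraction(c(0, 2.6e11, 1e13), p)
#' @export
available_site_fraction <- function(c, params) {
  stopifnot(inherits(params, "binding_params"))
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0))
    stop("'c' must be non-negative and finite")
  if (params$xi0 <= 1) return(rep(1, length(c)))
  # release fraction: 0 deep in the condensed regime, 1 above c_star
  s <- ifelse(c == 0, 0,
              plogis((log10(c) - log10(params$c_star)) /
                       params$transition_width))
  xi_eff <- params$xi0^(1 - s)       # geometric interpolation xi0 -> 1
  1 / xi_eff
}

## \int_0^c f(u) du by trapezoid on a log-spaced grid.  f is constant
## (1/xi0) below the grid start, so the head segment is analytic.
.site_integral <- function(conc, params, n_grid = 600L) {
  if (params$xi0 <= 1) return(conc)
  out <- numeric(length(conc))
  pos <- conc > 0
  if (!any(pos)) return(out)
  cmax <- max(conc[pos])
  c0 <- min(min(conc[pos]), params$c_star) * 1e-4
  grid <- exp(seq(log(c0), log(cmax), length.out = n_grid))
  fg <- available_site_fraction(grid, params)
  cum <- c(0, cumsum(diff(grid) * (fg[-1] + fg[-n_grid]) / 2))
  head <- c0 / params$xi0   # f ~ 1/xi0 on (0, c0]
  out[pos] <- head + approx(grid, cum, xout = conc[pos], rule = 2)$y
  out
}

#' Mean binding signal of the condensation model
#'
#' Noiseless mean dose-binding curve: bound particles accumulate over
#' the available sites and deplete them (Langmuir-like saturation),
#' `B(c) = b_max (1 - exp(-(slope_high/b_max) * integral_0^c f(u) du))`.
#'
#' @param c Particle concentrations in particles/mL (vectorized, >= 0).
#' @param params A [binding_params()] object.
#' @return Mean binding signal in % units.
#' @export
binding_mean <- function(c, params) {
  stopifnot(inherits(params, "binding_params"))
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0))
    stop("'c' must be non-negative and finite")
  I <- .site_integral(c, params)
  params$b_max * (1 - exp(-(params$slope_high / params$b_max) * I))
}

#' Dose-binding curve container
#'
#' A long-format data frame of per-replicate binding signals at ordered
#' particle concentrations, as produced by flow-cytometry dose series.
#'
#' @param concentration Particle concentrations in particles/mL
#'   (positive; strictly increasing within each replicate).
#' @param signal Binding readout (arbitrary fluorescence units, or % of
#'   maximum after [normalize_curve()]).
#' @param replicate Replicate identifier (integer; default all 1).
#' @param condition Text label, e.g. `"t24_control"`.
#'
#' @return A `data.frame` of class `dose_binding_curve` with columns
#'   `concentration`, `signal`, `replicate`, `condition`.
#' @export
dose_binding_curve <- function(concentration, signal, replicate = 1L,
                               condition = "custom") {
  if (length(concentration) == 0L) stop("empty dose list")
  if (!is.numeric(concentration) || any(!is.finite(concentration)) ||
      any(concentration <= 0))
    stop("concentrations must be positive and finite")
  if (length(signal) != length(concentration))
    stop("'signal' and 'concentration' must have equal length")
  replicate <- rep_len(as.integer(replicate), length(concentration))
  for (r in unique(replicate)) {
    cc <- concentration[replicate == r]
    if (is.unsorted(cc, strictly = TRUE))
      stop("concentrations must be strictly increasing within a replicate")
  }
  structure(data.frame(concentration = concentration,
                       signal = as.numeric(signal),
                       replicate = replicate,
                       condition = rep_len(as.character(condition),
                                           length(concentration))),
            class = c("dose_binding_curve", "data.frame"))
}

## per-dose means (and replicate variances) of a dose_binding_curve
.curve_means <- function(curve) {
  conc <- sort(unique(curve$concentration))
  m <- vapply(conc, function(ci) mean(curve$signal[curve$concentration == ci]),
              numeric(1))
  v <- vapply(conc, function(ci) {
    x <- curve$signal[curve$concentration == ci]
    if (length(x) > 1L) var(x) else NA_real_
  }, numeric(1))
  n <- vapply(conc, function(ci) sum(curve$concentration == ci), numeric(1))
  data.frame(concentration = conc, signal = m, var = v, n = n)
}

#' Simulate a dose-binding curve
#'
#' Forward-simulates the condensation binding model on a dose grid, with
#' mean-unbiased multiplicative log-normal noise of coefficient of
#' variation `noise_cv` (detector-gain-like fluorescence noise).
#'
#' @param params A [binding_params()] object.
#' @param concentrations Positive dose grid in particles/mL.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives the noiseless mean).
#' @param n_replicates Number of replicate curves (default 1).
#' @param seed Optional integer seed for reproducibility.
#' @param condition Condition label stored in the curve.
#' @return A [dose_binding_curve()].
#' @examples
#' p <- binding_params(4.2, 2.6e11, slope_high = 2.772e-10)
#' simulate_binding_curve(p, c(5e10, 2e11, 1e12), noise_cv = 0.05,
#'                        n_replicates = 4, seed = 1)
#' @export
simulate_binding_curve <- function(params, concentrations, noise_cv = 0,
                                   n_replicates = 1L, seed = NULL,
                                   condition = "custom") {
  stopifnot(inherits(params, "binding_params"))
  if (length(concentrations) == 0L) stop("empty dose list")
  if (any(concentrations <= 0)) stop("doses must be positive")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  concentrations <- sort(concentrations)
  mu <- binding_mean(concentrations, params)
  nrep <- as.integer(n_replicates)
  sig <- rep(mu, nrep)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    sig <- sig * exp(rnorm(length(sig), -sdlog^2 / 2, sdlog))
  }
  dose_binding_curve(rep(concentrations, nrep), sig,
                     replicate = rep(seq_len(nrep), each = length(mu)),
                     condition = condition)
}

#' Normalize a dose-binding curve to a 100% maximum
#'
#' Rescales all signals so that the maximum equals exactly 100 (the
#' convention used to compare cell lines with different absolute binding
#' capacity).  Idempotent.
#'
#' @param curve A [dose_binding_curve()].
#' @return The rescaled curve.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "dose_binding_curve"))
  mx <- max(curve$signal)
  if (!is.finite(mx) || mx <= 0)
    stop("cannot normalize: no positive signal in curve")
  curve$signal <- curve$signal * (100 / mx)
  curve
}

#' Initial dose-dependent binding slope
#'
#' Ordinary least-squares slope of signal against concentration through
#' the low-dose points, with the intercept fixed at 0 (unbound controls
#' define background zero).  The low-dose window is all doses below
#' `c_star/2` when `c_star` is supplied, otherwise the lowest
#' `n_lowest` doses.
#'
#' @param curve A [dose_binding_curve()] (normalized or raw).
#' @param c_star Optional critical concentration defining the window.
#' @param n_lowest Number of lowest doses used when `c_star` is absent
#'   (default 3).
#' @return A list with `slope`, `se` (standard error), `n_points` and
#'   `window` (the dose range used).
#' @export
initial_slope <- function(curve, c_star = NULL, n_lowest = 3L) {
  stopifnot(inherits(curve, "dose_binding_curve"))
  doses <- sort(unique(curve$concentration))
  if (!is.null(c_star)) {
    win <- doses[doses <= c_star / 2]
    if (length(win) < 3L) win <- doses[seq_len(min(3L, length(doses)))]
  } else {
    win <- doses[seq_len(min(n_lowest, length(doses)))]
  }
  sub <- curve[curve$concentration %in% win, ]
  if (nrow(sub) < 3L) stop("too few points in the low-dose window")
  if (all(sub$signal == 0))
    return(list(slope = 0, se = 0, n_points = nrow(sub), window = range(win)))
  fit <- lm(signal ~ 0 + concentration, data = sub)
  ## vcov warns on noiseless (perfect-fit) input; the SE is then 0
  list(slope = unname(coef(fit)[1]),
       se = unname(suppressWarnings(sqrt(diag(vcov(fit)))[1])),
       n_points = nrow(sub),
       window = range(win))
}

#' Cooperativity index of a dose-binding curve
#'
#' Ratio of the pre-saturation high-regime binding slope to the low-dose
#' slope.  Saturation is first linearized by transforming the signal to
#' `y = -b log(1 - B/b)` with `b` estimated from a two-parameter
#' saturating fit; the low slope is a zero-intercept OLS fit through the
#' two lowest doses, the high slope the largest pairwise difference
#' quotient among unsaturated doses.  In the sharp-transition limit of
#' the condensation model this ratio estimates `xi0`; curves with ratio
#' above `threshold` are classified cooperative.
#'
#' @param curve A [dose_binding_curve()] with at least 6 doses.
#' @param threshold Classification threshold (default 1.5, placing a
#'   weak-condensation curve at the boundary).
#' @return A list with `ratio`, `cooperative` (logical), `low_slope`,
#'   `high_slope` and `b_max_hat`.
#' @export
cooperativity_index <- function(curve, threshold = 1.5) {
  stopifnot(inherits(curve, "dose_binding_curve"))
  cm <- .curve_means(curve)
  if (nrow(cm) < 6L) stop("at least 6 doses are required")
  conc <- cm$concentration; y <- cm$signal
  if (max(y) <= 0) stop("curve has no positive signal")
  ## Estimate the saturation level from the high-dose regime: there the
  ## accumulation follows b*(1 - A*exp(-(s/b)*c)), with A absorbing the
  ## condensed-regime deficit, so the plateau is unbiased by the
  ## cooperative low-dose shape.
  n <- length(y)
  hi <- seq.int(n - 2L, n)   # plateau regime: the three highest doses
  b_hat <- tryCatch({
    dat_hi <- data.frame(ch = conc[hi], yh = y[hi])
    f0 <- minpack.lm::nlsLM(
      yh ~ b * (1 - A * exp(-(s / b) * ch)),
      data = dat_hi,
      start = list(b = max(y) * 1.1, A = 1, s = 2 * y[2] / conc[2]),
      lower = c(max(y) * 1.0001, 1e-3, 0), upper = c(Inf, 100, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    unname(coef(f0)["b"])
  }, error = function(e) NA_real_)
  if (is.finite(b_hat) && max(y) / b_hat > 0.3) {
    ystar <- -b_hat * log(pmax(1 - y / b_hat, 1e-8))
  } else {
    b_hat <- Inf
    ystar <- y   # no saturation reached: signal is already linear
  }
  usable <- if (is.finite(b_hat)) y < 0.95 * b_hat else rep(TRUE, n)
  if (sum(usable) < 4L) stop("curve is saturated: index unidentifiable")
  lo <- seq_len(2L)
  low_slope <- sum(ystar[lo] * conc[lo]) / sum(conc[lo]^2)
  dq <- diff(ystar) / diff(conc)
  ok <- usable[-1] & usable[-length(usable)]
  high_slope <- max(dq[ok])
  if (low_slope <= 0) stop("non-positive low-dose slope: index undefined")
  ratio <- high_slope / low_slope
  list(ratio = ratio, cooperative = ratio > threshold,
       low_slope = low_slope, high_slope = high_slope, b_max_hat = b_hat)
}

#' Glycan chain geometry for chain-length estimation
#'
#' Geometric conversion factors linking the critical particle
#' concentration to the glycan chain length.  Only `charges_per_nm` has
#' a default (4, the heparan sulphate value); the remaining factors
#' depend on the assay and must be supplied explicitly.
#'
#' @param charges_per_particle Glycan charges neutralized by one bound
#'   nanocapsule.
#' @param cells_per_ml Cell density during the binding assay (mL^-1).
#' @param chains_per_cell Glycosaminoglycan chains per cell.
#' @param charges_per_nm Linear charge density of the glycan (nm^-1,
#'   default 4).
#' @return An object of class `chain_geometry`.
#' @export
chain_geometry <- function(charges_per_particle, cells_per_ml,
                           chains_per_cell, charges_per_nm = 4) {
  vals <- c(charges_per_particle, cells_per_ml, chains_per_cell,
            charges_per_nm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry parameters must be positive and finite")
  structure(list(charges_per_particle = charges_per_particle,
                 cells_per_ml = cells_per_ml,
                 chains_per_cell = chains_per_cell,
                 charges_per_nm = charges_per_nm),
            class = "chain_geometry")
}

#' Glycan chain length from the critical concentration
#'
#' Charge-balance estimate of the chain contour length: at the critical
#' concentration the particles neutralize the condensed charge, so
#' `L = (c_star * charges_per_particle) /
#' (cells_per_ml * chains_per_cell * charges_per_nm)`.  Linear in
#' `c_star` for fixed geometry, so length ratios between conditions
#' equal their `c_star` ratios.
#'
#' @param c_star Critical particle concentration (particles/mL).
#' @param geometry A [chain_geometry()] object.
#' @return Estimated chain length in nm.
#' @export
estimate_chain_length <- function(c_star, geometry) {
  stopifnot(inherits(geometry, "chain_geometry"))
  if (!is.numeric(c_star) || any(c_star <= 0))
    stop("'c_star' must be positive")
  (c_star * geometry$charges_per_particle) /
    (geometry$cells_per_ml * geometry$chains_per_cell *
       geometry$charges_per_nm)
}
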