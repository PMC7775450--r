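#' Hill parameters for vacuole-formation kinetics
#'
#' @param nv_max Maximum vacuole signal (area fraction per cell, >= 0).
#' @param k_half Half-maximum time in hours (> 0); its inverse is the
#'   capsaicin-deposition ability.
#' @param n_hill Dimensionless Hill exponent (> 0).
#' @return An object of class `hill_params`.
#' @examples
#' hill_params(nv_max = 0.2, k_half = 6, n_hill = 2.5)
#' @export
hill_params <- function(nv_max, k_half, n_hill) {
  stopifnot(is.numeric(nv_max), length(nv_max) == 1L, nv_max >= 0,
            is.numeric(k_half), length(k_half) == 1L, k_half > 0,
            is.numeric(n_hill), length(n_hill) == 1L, n_hill > 0)
  structure(list(nv_max = nv_max, k_half = k_half, n_hill = n_hill),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill kinetics: nv_max = %.4g, k_half = %.4g h, n = %.4g\n",
              x$nv_max, x$k_half, x$n_hill))
  invisible(x)
}

#' Hill-type vacuole formation model
#'
#' Time course of vacuole formation after nanocapsule treatment:
#' `N_v(t) = nv_max * t^n / (k_half^n + t^n)`.  Zero at `t = 0`,
#' monotone non-decreasing, `nv_max/2` at `t = k_half` for any exponent,
#' and saturating at `nv_max`.
#'
#' @param t Times in hours (>= 0; vectorized).
#' @param params A [hill_params()] object.
#' @return Vacuole signal at each time.
#' @examples
#' hill_vacuole_model(c(0, 6, 24), hill_params(0.2, 6, 2.5))
#' @export
hill_vacuole_model <- function(t, params) {
  stopifnot(inherits(params, "hill_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("'t' must be non-negative and finite")
  tn <- t^params$n_hill
  params$nv_max * tn / (params$k_half^params$n_hill + tn)
}

#' Vacuole time-course container
#'
#' @param times Strictly increasing times in hours, starting at >= 0
#'   (treatment defines t = 0).
#' @param values Vacuole area normalized to cell count.
#' @param condition Text label (cell line and dose).
#' @return A `data.frame` of class `vacuole_timecourse` with columns
#'   `time_h`, `value`, `condition`.
#' @export
vacuole_timecourse <- function(times, values, condition = "custom") {
  if (!is.numeric(times) || any(times < 0) ||
      is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing and start at >= 0")
  if (length(values) != length(times))
    stop("'values' and 'times' must have equal length")
  structure(data.frame(time_h = times, value = as.numeric(values),
                       condition = rep_len(as.character(condition),
                                           length(times))),
            class = c("vacuole_timecourse", "data.frame"))
}

#' Fit Hill vacuole-formation kinetics
#'
#' Nonlinear least squares of the Hill model against a vacuole
#' time-course, yielding the deposition-ability metric
#' `k_inv = 1/k_half`.  Convergence failure is a reported outcome, not
#' an exception: a fit counts as converged only if the optimizer
#' succeeded, the `nv_max` standard error is smaller than the estimate,
#' and `k_half` lies inside the observed time span — otherwise no
#' reliable vacuole formation is detectable (flat or near-zero series
#' behave this way).
#'
#' @param tc A [vacuole_timecourse()] with at least 5 time points.
#' @param init Optional [hill_params()] starting values; default
#'   heuristics are `nv_max = max(value)`, `k_half` = first time
#'   exceeding half of that, `n = 2`.
#' @return An object of class `hill_fit` with `params` ([hill_params()]
#'   estimates), `k_inv`, `se`, `converged` and the `nls` object.
#' @examples
#' tt <- seq(0, 10, by = 1/12)
#' tc <- vacuole_timecourse(tt, hill_vacuole_model(tt, hill_params(0.2, 6, 2.5)))
#' fit_vacuole_kinetics(tc)
#' @export
fit_vacuole_kinetics <- function(tc, init = NULL) {
  stopifnot(inherits(tc, "vacuole_timecourse"))
  if (nrow(tc) < 5L) stop("at least 5 time points are required")
  t <- tc$time_h; y <- tc$value
  failed <- function() structure(
    list(params = NULL, k_inv = NA_real_, se = NULL,
         converged = FALSE, fit = NULL, data = tc),
    class = "hill_fit")
  if (max(y) <= 0 || sd(y) == 0) return(failed())

  if (is.null(init)) {
    nv0 <- max(y)
    above <- t[y >= nv0 / 2 & t > 0]
    k0 <- if (length(above)) min(above) else stats::median(t[t > 0])
    init <- hill_params(nv0, max(k0, min(t[t > 0])), 2)
  }
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ nv_max * ifelse(t > 0, t^n / (k^n + t^n), 0),
      data = dat,
      start = list(nv_max = init$nv_max, k = init$k_half, n = init$n_hill),
      lower = c(0, 1e-6, 0.1), upper = c(Inf, Inf, 20),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())

  est <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, 3))
  names(se) <- names(est)
  ok <- isTRUE(fit$convInfo$isConv) &&
    is.finite(se["nv_max"]) && se["nv_max"] < est["nv_max"] &&
    est["k"] >= min(t) && est["k"] <= max(t)

  structure(list(
    params = hill_params(unname(est["nv_max"]), unname(est["k"]),
                         unname(est["n"])),
    k_inv = unname(1 / est["k"]),
    se = c(nv_max = unname(se["nv_max"]), k_half = unname(se["k"]),
           n_hill = unname(se["n"]),
           k_inv = unname(se["k"] / est["k"]^2)),
    converged = isTRUE(ok),
    fit = fit, data = tc
  ), class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) {
  if (is.null(object$params)) return(NULL)
  c(nv_max = object$params$nv_max, k_half = object$params$k_half,
    n_hill = object$params$n_hill, k_inv = object$k_inv)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill vacuole-kinetics fit\n")
  if (is.null(x$params)) {
    cat("  converged: FALSE (no vacuole formation detectable)\n")
    return(invisible(x))
  }
  cat(sprintf("  nv_max: %.4g (SE %.2g)\n", x$params$nv_max, x$se["nv_max"]))
  cat(sprintf("  k_half: %.4g h (SE %.2g)\n", x$params$k_half, x$se["k_half"]))
  cat(sprintf("  n:      %.4g (SE %.2g)\n", x$params$n_hill, x$se["n_hill"]))
  cat(sprintf("  deposition ability k^-1: %.4g h^-1\n", x$k_inv))
  cat(sprintf("  converged: %s\n", x$converged))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$params)) stop("fit did not converge")
  t <- if (is.null(newdata)) object$data$time_h
       else if (is.data.frame(newdata)) newdata$time_h else newdata
  hill_vacuole_model(t, object$params)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  if (is.null(object$params)) stop("fit did not converge")
  object$data$value - predict(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  plot(x$data$time_h, x$data$value, xlab = "time (h)",
       ylab = "vacuole area per cell", pch = 1, ...)
  if (!is.null(x$params)) {
    tt <- seq(min(x$data$time_h), max(x$data$time_h), length.out = 200)
    lines(tt, hill_vacuole_model(tt, x$params), col = "red3")
    abline(v = x$params$k_half, lty = 2, col = "grey40")
  }
  invisible(x)
}
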