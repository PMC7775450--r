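#' Read a dose-binding CSV table
#'
#' Reads the project dose-binding format: header columns
#' `concentration_particles_per_ml, signal, replicate, condition`
#' (decimal point, scientific notation accepted).  Within each replicate
#' concentrations must be increasing; unsorted rows are sorted with a
#' warning, or rejected under `strict = TRUE`.
#'
#' @param path Path to the CSV file.
#' @param strict Reject unsorted concentrations instead of sorting
#'   (default FALSE).
#' @return A [dose_binding_curve()].
#' @export
read_dose_table <- function(path, strict = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_particles_per_ml", "signal")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(d$concentration_particles_per_ml) || !is.numeric(d$signal)) {
    bad <- which(is.na(suppressWarnings(
      as.numeric(d$concentration_particles_per_ml))) |
        is.na(suppressWarnings(as.numeric(d$signal))))
    stop("non-numeric cell(s) at row(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(d$replicate)) d$replicate <- 1L
  if (is.null(d$condition)) d$condition <- "unknown"
  for (r in unique(d$replicate)) {
    cc <- d$concentration_particles_per_ml[d$replicate == r]
    if (is.unsorted(cc, strictly = TRUE)) {
      if (strict)
        stop("concentrations not strictly increasing in replicate ", r)
      warning("sorting concentrations in replicate ", r)
      ord <- order(d$concentration_particles_per_ml)
      d <- d[ord, ]
      break
    }
  }
  ## interleave so each replicate's doses are increasing
  d <- d[order(d$replicate, d$concentration_particles_per_ml), ]
  dose_binding_curve(d$concentration_particles_per_ml, d$signal,
                     replicate = d$replicate, condition = d$condition)
}

#' Write a dose-binding curve to CSV
#'
#' @param curve A [dose_binding_curve()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dose_table <- function(curve, path) {
  stopifnot(inherits(curve, "dose_binding_curve"))
  out <- data.frame(
    concentration_particles_per_ml = format(curve$concentration,
                                            scientific = TRUE, digits = 15),
    signal = curve$signal,
    replicate = curve$replicate,
    condition = curve$condition)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time-series CSV table
#'
#' Format `time_h, value, replicate, condition`.  Returns one
#' [vacuole_timecourse()] per replicate.
#'
#' @param path Path to the CSV file.
#' @return A list of [vacuole_timecourse()] objects, one per replicate.
#' @export
read_timeseries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(d$replicate)) d$replicate <- 1L
  if (is.null(d$condition)) d$condition <- "unknown"
  lapply(split(d, d$replicate), function(s) {
    s <- s[order(s$time_h), ]
    vacuole_timecourse(s$time_h, s$value, condition = s$condition[1])
  })
}

#' Write time-courses to a time-series CSV
#'
#' @param tcs A [vacuole_timecourse()] or list of them (replicates).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(tcs, path) {
  if (inherits(tcs, "vacuole_timecourse")) tcs <- list(tcs)
  rows <- do.call(rbind, lapply(seq_along(tcs), function(i)
    data.frame(time_h = tcs[[i]]$time_h, value = tcs[[i]]$value,
               replicate = i, condition = tcs[[i]]$condition)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a raw ECIS CSV table
#'
#' Format `time_h, impedance_ohm, well, frequency_hz, condition`.
#'
#' @param path Path to the CSV file.
#' @return A data frame split-ready by well, sorted by time.
#' @export
read_ecis_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "impedance_ohm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(d$well)) d$well <- "A1"
  if (is.null(d$frequency_hz)) d$frequency_hz <- NA_real_
  if (is.null(d$condition)) d$condition <- "unknown"
  d[order(d$well, d$time_h), ]
}

#' Build an analysis report
#'
#' Serializable record of one analysis stage: parameter estimates with
#' standard errors, the convergence flag, and provenance (seed, input,
#' package version).
#'
#' @param stage Stage name, e.g. `"binding_fit"`.
#' @param estimates Named numeric vector of estimates.
#' @param se Named numeric vector of standard errors (same names).
#' @param converged Logical convergence flag.
#' @param seed Seed used (or `NA`).
#' @param input Input description or path.
#' @return An object of class `analysis_report`.
#' @export
analysis_report <- function(stage, estimates, se = NULL, converged = NA,
                            seed = NA_integer_, input = "") {
  structure(list(
    stage = stage,
    parameters = list(estimate = as.list(estimates),
                      se = as.list(if (is.null(se))
                        setNames(rep(NA_real_, length(estimates)),
                                 names(estimates)) else se)),
    converged = converged,
    provenance = list(seed = seed, input = input,
                      package_version = as.character(
                        utils::packageVersion("glycobind")))
  ), class = "analysis_report")
}

#' Write an analysis report to JSON
#'
#' @param report An [analysis_report()] or plain list.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an analysis report from JSON
#'
#' @param path Path to a JSON report.
#' @return An `analysis_report`.
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report: stage '%s' (converged: %s)\n",
              x$stage, x$converged))
  est <- unlist(x$parameters$estimate)
  se <- unlist(x$parameters$se)
  for (nm in names(est))
    cat(sprintf("  %-12s %.5g (SE %.3g)\n", nm, est[[nm]],
                if (nm %in% names(se)) se[[nm]] else NA))
  cat(sprintf("  seed %s, package %s\n", x$provenance$seed,
              x$provenance$package_version))
  invisible(x)
}

#' Run a simulate-fit-report pipeline
#'
#' Executes the analysis chains described by a configuration: for each
#' stage entry, generates the synthetic dataset, runs the matching fit,
#' and collects an [analysis_report()].  Non-convergence is a reported
#' result, not an error.  Config entries are lists with fields `stage`
#' (`"binding"`, `"vacuole"` or `"ecis"`), `scenario` and optional
#' `seed` and noise settings; a YAML file path is accepted when the
#' yaml package is installed.
#'
#' @param config A list of stage configs, or a path to a YAML file with
#'   a top-level `stages:` list.
#' @return A list of `analysis_report` objects, one per stage entry.
#' @examples
#' reports <- run_pipeline(list(
#'   list(stage = "binding", scenario = "t24_control", seed = 7),
#'   list(stage = "vacuole", scenario = "t24", seed = 7)))
#' reports[[1]]
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)$stages
  }
  if (!is.list(config) || !length(config)) stop("empty pipeline config")
  lapply(config, function(cfg) {
    if (is.null(cfg$stage)) stop("config entry without a 'stage' field")
    seed <- if (is.null(cfg$seed)) NA_integer_ else as.integer(cfg$seed)
    switch(cfg$stage,
      binding = {
        cur <- gen_binding_dataset(
          scenario = cfg$scenario %||% "t24_control",
          noise_cv = cfg$noise_cv %||% 0.05,
          n_replicates = cfg$n_replicates %||% 4L,
          seed = seed)
        fit <- fit_condensation_model(normalize_curve(cur))
        analysis_report("binding_fit", fit$estimates, fit$se,
                        fit$converged, seed,
                        input = paste0("scenario:", cur$condition[1]))
      },
      vacuole = {
        tcs <- gen_vacuole_timecourse(
          scenario = cfg$scenario %||% "t24",
          dose_uM = cfg$dose_uM %||% 250,
          noise_cv = cfg$noise_cv %||% 0.05,
          n_replicates = cfg$n_replicates %||% 3L,
          seed = seed)
        fit <- fit_vacuole_kinetics(average_timecourses(tcs))
        analysis_report("vacuole_fit", coef(fit),
                        converged = fit$converged, seed = seed,
                        input = paste0("scenario:", tcs[[1]]$condition[1]))
      },
      ecis = {
        raw <- gen_impedance_trace(
          scenario = cfg$scenario %||% "t24",
          noise_sd = cfg$noise_sd %||% 0.02, seed = seed)
        tr <- normalize_impedance(raw$time_h, raw$impedance_ohm,
                                  treatment_time = attr(raw, "treatment_time"),
                                  frequency = attr(raw, "frequency"),
                                  condition = cfg$scenario %||% "t24")
        fit <- fit_impedance(tr)
        analysis_report("ecis_fit", coef(fit),
                        converged = fit$converged, seed = seed,
                        input = paste0("scenario:", cfg$scenario %||% "t24"))
      },
      stop("unknown pipeline stage: ", cfg$stage))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a TIFF image stack
#'
#' Thin wrappers over the tiff package for single- and multi-page
#' grayscale TIFFs, returning/consuming [image_stack()] objects.
#' Intensities are stored as floats in `[0, 1]` in the file.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval,channel Calibration passed to
#'   [image_stack()] on read.
#' @return `read_image_stack`: an [image_stack()];
#'   `write_image_stack`: the path, invisibly.
#' @export
read_image_stack <- function(path, pixel_size, frame_interval = NA_real_,
                             channel = "fluorescence") {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("TIFF I/O requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # first channel only
    p * 255
  })
  image_stack(frames, pixel_size = pixel_size,
              frame_interval = frame_interval, channel = channel)
}

#' @param stack An [image_stack()] (for `write_image_stack`).
#' @rdname read_image_stack
#' @export
write_image_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("TIFF I/O requires the 'tiff' package")
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[3]
  pages <- lapply(seq_len(n), function(i)
    pmin(pmax(stack$frames[, , i] / 255, 0), 1))
  tiff::writeTIFF(pages, path)
  invisible(path)
}
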