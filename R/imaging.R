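#' Image stack container
#'
#' Ordered grayscale frames with physical calibration.  Frames are
#' stored as an `height x width x n` numeric array; intensities may be
#' 8-bit (0..255) or floats in `[0, 1]` (converted to 8-bit before
#' histogram-based thresholding).
#'
#' @param frames A list of equal-sized numeric matrices, or a 3-D array.
#' @param pixel_size Physical pixel size in micrometres (> 0).
#' @param frame_interval Time between frames in hours.
#' @param channel `"phase_contrast"` or `"fluorescence"`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval = NA_real_,
                        channel = c("phase_contrast", "fluorescence")) {
  channel <- match.arg(channel)
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must have the same shape")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3L) stop("'frames' must be a 3-D array or list")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be positive (micrometres)")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d frame(s) of %dx%d px (%s), %g um/px",
              d[3], d[1], d[2], x$channel, x$pixel_size))
  if (is.finite(x$frame_interval))
    cat(sprintf(", %g h between frames", x$frame_interval))
  cat("\n")
  invisible(x)
}

## 256-bin histogram of an 8-bit-converted frame
.to_8bit <- function(frame) {
  if (max(frame) <= 1 && min(frame) >= 0) frame <- frame * 255
  pmin(pmax(round(frame), 0), 255)
}

.hist256 <- function(frame8) {
  tabulate(as.integer(frame8) + 1L, nbins = 256L)
}

## ImageJ-style "Mean" threshold: the histogram mean, floored.
.threshold_mean <- function(h) {
  lev <- 0:255
  floor(sum(h * lev) / sum(h))
}

## Zack triangle threshold on a 256-bin histogram.  A line is drawn from
## the histogram peak to the far end of the longer tail; the threshold is
## the bin at maximal distance below that line.  If the longer tail lies
## to the left, the histogram is mirrored first.  Ties break toward the
## lower threshold.
.threshold_triangle <- function(h) {
  nz <- which(h > 0)
  lo <- min(nz) - 1L; hi <- max(nz) - 1L    # 0-based bin indices
  peak <- which.max(h) - 1L
  flipped <- (peak - lo) > (hi - peak)      # longer tail on the left
  if (flipped) {
    h <- rev(h)
    peak <- 255L - peak
    hi <- 255L - lo
  }
  hpeak <- h[peak + 1L]
  if (hi <= peak) return(if (flipped) 255L - peak else peak)
  idx <- (peak + 1L):hi
  ## cross-product distance from (i, h[i]) to the line (peak,hpeak)->(hi,0)
  d <- (hi - peak) * (hpeak - h[idx + 1L]) - hpeak * (idx - peak)
  split <- idx[which.max(d)]
  if (flipped) 255L - split else split
}

#' Automatic histogram thresholding
#'
#' Binarizes a grayscale frame with one of the two ImageJ auto-threshold
#' variants used for live-cell quantification: `"mean_dark"` (threshold
#' at the histogram mean) or `"triangle_dark"` (Zack triangle geometry
#' on the 256-bin histogram, ties broken toward the lower threshold).
#' The `dark` polarity means dark background: pixels strictly above the
#' threshold are foreground.
#'
#' @param frame A numeric matrix (8-bit 0..255, or floats in `[0, 1]`).
#' @param method `"mean_dark"` or `"triangle_dark"`.
#' @return A logical matrix (`TRUE` = foreground) with the threshold
#'   (8-bit level) attached as attribute `"threshold"`.
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 14)), 8, 8)
#' table(auto_threshold(img, "mean_dark"))
#' @export
auto_threshold <- function(frame, method = c("mean_dark", "triangle_dark")) {
  method <- match.arg(method)
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("'frame' must be a numeric matrix")
  f8 <- .to_8bit(frame)
  if (max(f8) == min(f8))
    stop("degenerate input: constant image cannot be thresholded")
  h <- .hist256(f8)
  thr <- switch(method,
                mean_dark = .threshold_mean(h),
                triangle_dark = .threshold_triangle(h))
  mask <- f8 > thr
  attr(mask, "threshold") <- thr
  mask
}

## binarize tolerating already-binary and constant frames: binary input
## ({0,1} or {0,255}) passes through, constant frames are all background
.binarize_or_empty <- function(frame, method) {
  f8 <- .to_8bit(frame)
  u <- unique(as.vector(f8))
  if (all(u %in% c(0, 255))) return(f8 > 0)
  if (max(f8) == min(f8)) {
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  auto_threshold(frame, method)
}

#' Frame-difference motility index
#'
#' Quantifies cell-layer dynamics from a phase-contrast time-lapse: each
#' frame is binarized with the mean-dark threshold, the per-pixel
#' standard deviation image of every consecutive frame pair is computed
#' (population normalization, matching a 2-slice z-projection), and the
#' index is the mean brightness of that SD image.  Higher values mean
#' more frame-to-frame change, proportional to the migratory potential
#' of the layer.
#'
#' @param stack An [image_stack()] with at least 2 frames.
#' @return A list of class `motility_result` with `index_series`
#'   (length `n_frames - 1`) and `n_transitions`.
#' @export
motility_index <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[3]
  if (n < 2L) stop("at least 2 frames are required")
  masks <- lapply(seq_len(n), function(i)
    .binarize_or_empty(stack$frames[, , i], "mean_dark") * 1)
  idx <- vapply(seq_len(n - 1L), function(i) {
    a <- masks[[i]]; b <- masks[[i + 1L]]
    mean(abs(a - b) / 2)       # population SD of two binary slices
  }, numeric(1))
  structure(list(index_series = idx, n_transitions = n - 1L),
            class = "motility_result")
}

#' @export
print.motility_result <- function(x, ...) {
  cat(sprintf("Motility index over %d transitions: mean %.4g (range %.4g-%.4g)\n",
              x$n_transitions, mean(x$index_series),
              min(x$index_series), max(x$index_series)))
  invisible(x)
}

#' Vacuole area per cell from a fluorescence stack
#'
#' Per frame, segments bright vacuoles with the triangle-dark threshold
#' and reports the foreground area (converted to square micrometres via
#' the pixel size) divided by the number of cells in the field.  Frames
#' with no intensity structure contribute zero area.  The result is a
#' [vacuole_timecourse()] ready for [fit_vacuole_kinetics()].
#'
#' @param stack A fluorescence [image_stack()] with a finite
#'   `frame_interval`.
#' @param n_cells Average number of cells in the field of view (>= 1).
#' @param condition Label stored in the time course.
#' @return A [vacuole_timecourse()] (times in hours from the first
#'   frame).
#' @export
vacuole_area_fraction <- function(stack, n_cells, condition = "custom") {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(n_cells) || n_cells < 1) stop("'n_cells' must be >= 1")
  n <- dim(stack$frames)[3]
  px_area_um2 <- stack$pixel_size^2
  areas <- vapply(seq_len(n), function(i) {
    m <- .binarize_or_empty(stack$frames[, , i], "triangle_dark")
    sum(m) * px_area_um2 / n_cells
  }, numeric(1))
  dt <- if (is.finite(stack$frame_interval)) stack$frame_interval else 1
  vacuole_timecourse(seq(0, by = dt, length.out = n), areas,
                     condition = condition)
}

## separable Gaussian blur with replicate-edge padding
.gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad_conv <- function(m) {     # convolve rows of m with k
    n <- nrow(m)
    mp <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Detect glycan clusters in a super-resolution image
#'
#' Spot detection for STED-like point patterns.  The image is band-pass
#' filtered (Gaussian smoothing matched to a fraction of the spot size,
#' robust background removal), then spots are extracted greedily: the
#' brightest remaining peak is localized to sub-pixel precision
#' (parabolic interpolation), its point-spread-function contribution is
#' subtracted (deflation), and the search repeats until the residual
#' falls below a robust intensity cut.  Deflation resolves partially
#' overlapping spots down to roughly the PSF width; a minimum-separation
#' rule suppresses duplicate detections of one spot.  Reports the
#' cluster count, density per square micrometre and mean
#' nearest-neighbour spacing in nm.
#'
#' @param image Numeric matrix of intensities (photon counts or a.u.).
#' @param pixel_size Pixel size in nm (default 20, typical STED voxel).
#' @param fwhm Expected spot full width at half maximum in nm
#'   (default 60).
#' @param threshold_sd Robust z-cut: peaks must exceed the image
#'   background by this many MADs of the smoothed image (default 6).
#' @param min_separation Minimum centre-to-centre distance in nm;
#'   closer re-detections are treated as duplicates (default
#'   `2 * fwhm / 3`).
#' @param smooth_frac Noise-suppression smoothing sigma as a fraction
#'   of the PSF sigma (default 0.5).
#' @return A list of class `cluster_result` with `n_clusters`,
#'   `density` (per um^2), `mean_spacing` (nm, `NA` when fewer than two
#'   clusters), `spot_coordinates` (data frame, nm) and
#'   `analyzed_area` (um^2).
#' @export
detect_clusters <- function(image, pixel_size = 20, fwhm = 60,
                            threshold_sd = 6, min_separation = NULL,
                            smooth_frac = 0.5) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix")
  area_um2 <- prod(dim(image)) * (pixel_size / 1000)^2
  empty <- function() structure(
    list(n_clusters = 0L, density = 0, mean_spacing = NA_real_,
         spot_coordinates = data.frame(x_nm = numeric(0), y_nm = numeric(0)),
         analyzed_area = area_um2),
    class = "cluster_result")
  if (max(image) == min(image)) return(empty())
  if (is.null(min_separation)) min_separation <- 2 * fwhm / 3

  sigma_psf <- (fwhm / 2.3548) / pixel_size
  ss <- smooth_frac * sigma_psf
  W <- .gaussian_blur(image, ss)
  bg <- stats::median(W)
  thr0 <- threshold_sd * stats::mad(W)
  st <- sqrt(sigma_psf^2 + ss^2)   # spot sigma in the smoothed image
  r <- ceiling(4 * st)
  nr <- nrow(W); nc <- ncol(W)
  Wr <- W - bg
  ## prominence floor: on (near-)noiseless images the MAD collapses to
  ## zero; never accept peaks below 10% of the brightest spot
  thr0 <- max(thr0, 0.1 * max(Wr))
  min_sep_px <- min_separation / pixel_size
  pts <- matrix(0, 0, 2)
  max_iter <- 20L + 10L * ceiling(area_um2 * 100)
  for (it in seq_len(max_iter)) {
    i <- which.max(Wr)
    A <- Wr[i]
    if (A < thr0) break
    ri <- (i - 1L) %% nr + 1L; ci <- (i - 1L) %/% nr + 1L
    dy <- 0; dx <- 0   # parabolic sub-pixel refinement
    if (ri > 1L && ri < nr) {
      a <- Wr[ri - 1L, ci]; b <- Wr[ri, ci]; cc <- Wr[ri + 1L, ci]
      den <- a - 2 * b + cc
      if (den < 0) dy <- 0.5 * (a - cc) / den
    }
    if (ci > 1L && ci < nc) {
      a <- Wr[ri, ci - 1L]; b <- Wr[ri, ci]; cc <- Wr[ri, ci + 1L]
      den <- a - 2 * b + cc
      if (den < 0) dx <- 0.5 * (a - cc) / den
    }
    cy <- ri + dy; cx <- ci + dx
    if (nrow(pts) == 0L ||
        min((pts[, 1] - cy)^2 + (pts[, 2] - cx)^2) >= min_sep_px^2)
      pts <- rbind(pts, c(cy, cx))
    r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r))
    c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r))
    gy <- exp(-((r0:r1) - cy)^2 / (2 * st^2))
    gx <- exp(-((c0:c1) - cx)^2 / (2 * st^2))
    Wr[r0:r1, c0:c1] <- Wr[r0:r1, c0:c1] - A * outer(gy, gx)
  }
  n <- nrow(pts)
  if (n == 0L) return(empty())
  xy <- cbind(x_nm = (pts[, 2] - 0.5) * pixel_size,
              y_nm = (pts[, 1] - 0.5) * pixel_size)
  spacing <- if (n >= 2L) {
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  } else NA_real_

  structure(list(n_clusters = n, density = n / area_um2,
                 mean_spacing = spacing,
                 spot_coordinates = as.data.frame(xy),
                 analyzed_area = area_um2),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Detected %d clusters in %.3g um^2: density %.3g um^-2",
              x$n_clusters, x$analyzed_area, x$density))
  if (is.finite(x$mean_spacing))
    cat(sprintf(", mean NN spacing %.3g nm", x$mean_spacing))
  cat("\n")
  invisible(x)
}
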