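# Image-quality metrics: ROI-based contrast-to-noise ratio and power-spectrum
# spatial resolution.

#' Rectangular ROI (half-open, 0-based pixel coordinates)
#'
#' `x` runs along columns, `y` along rows; the rectangle covers pixels with
#' `x0 <= x < x1`, `y0 <= y < y1` (the convention used in the YAML/JSON ROI
#' files).
#'
#' @param x0,y0,x1,y1 Corner coordinates, integers with `x1 > x0`, `y1 > y0`.
#' @return Object of class `roi`.
#' @export
roi <- function(x0, y0, x1, y1) {
  if (x1 <= x0 || y1 <= y0) stop("ROI must be non-empty (x1 > x0, y1 > y0)")
  if (x0 < 0 || y0 < 0) stop("ROI coordinates are 0-based and non-negative")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)), class = "roi")
}

#' Signal / reference / noise ROI triplet
#'
#' The three boxes of the CNR definition: the signal ROI (e.g. inside the
#' iodine tube), a reference ROI in background tissue, and a noise ROI whose
#' pixel standard deviation estimates sigma_BG. Signal and reference must not
#' overlap the noise ROI.
#'
#' @param signal_roi,reference_roi,noise_roi [roi()] objects.
#' @return Object of class `roi_set`.
#' @export
roi_set <- function(signal_roi, reference_roi, noise_roi) {
  for (r in list(signal_roi, reference_roi, noise_roi))
    stopifnot(inherits(r, "roi"))
  overlaps <- function(a, b)
    a$x0 < b$x1 && b$x0 < a$x1 && a$y0 < b$y1 && b$y0 < a$y1
  if (overlaps(signal_roi, noise_roi) || overlaps(reference_roi, noise_roi))
    stop("signal/reference ROIs must not overlap the noise ROI")
  structure(list(signal_roi = signal_roi, reference_roi = reference_roi,
                 noise_roi = noise_roi), class = "roi_set")
}

#' Read an ROI set from YAML or JSON
#'
#' Expects keys `signal_roi`, `reference_roi`, `noise_roi`, each with
#' `x0, y0, x1, y1` (half-open, 0-based).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [roi_set()].
#' @export
read_roi_set <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(r) roi(r$x0, r$y0, r$x1, r$y1)
  roi_set(mk(lst$signal_roi), mk(lst$reference_roi), mk(lst$noise_roi))
}

.roi_pixels <- function(image, r) {
  if (r$x1 > ncol(image) || r$y1 > nrow(image))
    stop("ROI extends outside the image")
  image[(r$y0 + 1):r$y1, (r$x0 + 1):r$x1, drop = FALSE]
}

#' Contrast-to-noise ratio
#'
#' `CNR = (mean(signal) - mean(reference)) / sd(noise)` with the sample
#' standard deviation over the noise ROI. Invariant under affine intensity
#' rescaling with positive gain.
#'
#' @param image Numeric matrix.
#' @param rois A [roi_set()].
#' @return CNR (unitless scalar).
#' @export
cnr <- function(image, rois) {
  stopifnot(is.matrix(image), inherits(rois, "roi_set"))
  s1 <- mean(.roi_pixels(image, rois$signal_roi))
  s2 <- mean(.roi_pixels(image, rois$reference_roi))
  ns <- .roi_pixels(image, rois$noise_roi)
  if (length(ns) < 2) stop("noise ROI needs at least 2 pixels")
  sg <- stats::sd(as.vector(ns))
  if (sg == 0) stop("zero noise standard deviation: CNR undefined on a constant image")
  (s1 - s2) / sg
}

#' Sub-block standard error of the CNR
#'
#' Splits each ROI into `n_splits` contiguous blocks along its longer axis,
#' computes one CNR per block triplet, and reports
#' `sd(block CNRs) / sqrt(n_splits)`. Because each block has `1/n_splits` of
#' the ROI area, the block CNRs scatter about sqrt(n_splits) times more than
#' the full-ROI CNR, so this estimator targets the standard error of the
#' full-ROI CNR and is approximately independent of `n_splits`.
#'
#' @param image Numeric matrix.
#' @param rois A [roi_set()].
#' @param n_splits Number of sub-blocks (>= 2 for an estimate; `1` returns
#'   `NA` with a warning).
#' @return Non-negative standard error (scalar), deterministic for fixed
#'   inputs.
#' @export
cnr_uncertainty <- function(image, rois, n_splits = 4L) {
  stopifnot(is.matrix(image), inherits(rois, "roi_set"))
  n_splits <- as.integer(n_splits)
  if (n_splits < 1L) stop("n_splits must be >= 1")
  if (n_splits == 1L) {
    warning("CNR uncertainty is not estimable from a single block")
    return(NA_real_)
  }
  split_roi <- function(r) {
    w <- r$x1 - r$x0; h <- r$y1 - r$y0
    along_x <- w >= h
    n <- if (along_x) w else h
    if (n < n_splits)
      stop(sprintf("ROI of %d pixels along its longer axis cannot be split %d ways",
                   n, n_splits))
    cuts <- round(seq(0, n, length.out = n_splits + 1))
    lapply(seq_len(n_splits), function(k) {
      if (along_x) roi(r$x0 + cuts[k], r$y0, r$x0 + cuts[k + 1], r$y1)
      else roi(r$x0, r$y0 + cuts[k], r$x1, r$y0 + cuts[k + 1])
    })
  }
  ss <- split_roi(rois$signal_roi)
  rr <- split_roi(rois$reference_roi)
  nn <- split_roi(rois$noise_roi)
  vals <- vapply(seq_len(n_splits), function(k)
    cnr(image, roi_set(ss[[k]], rr[[k]], nn[[k]])), numeric(1))
  stats::sd(vals) / sqrt(n_splits)
}

#' Spatial resolution from the image power spectrum
#'
#' Computes the 2-D power spectrum `|FFT|^2` (after mean removal), smooths it
#' with a Gaussian of standard deviation `smoothing` frequency-grid pixels,
#' radially averages it into 1-D bins up to the Nyquist frequency, estimates
#' the noise baseline as the median radial power over the top 10% of
#' frequencies below Nyquist, and returns the maximum spatial frequency
#' (lp/mm) at which the smoothed radial power is at least twice that
#' baseline.
#'
#' @param image Numeric matrix, at least 64 x 64 pixels.
#' @param pixel_pitch_um Pixel pitch in micrometres.
#' @param smoothing Gaussian kernel standard deviation in frequency-grid
#'   pixels (default 0.9).
#' @return Resolution in lp/mm (in `(0, Nyquist]`); if no frequency clears
#'   twice the baseline the lowest bin frequency is returned with a warning.
#' @export
resolution_power_spectrum <- function(image, pixel_pitch_um = 71,
                                      smoothing = 0.9) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 64 || ncol(image) < 64)
    stop("image must be at least 64 x 64 pixels")
  if (stats::sd(as.vector(image)) == 0)
    stop("constant image carries no signal: resolution undefined")
  nr <- nrow(image); nc <- ncol(image)
  P <- Mod(stats::fft(image - mean(image)))^2
  if (smoothing > 0) {
    # circular Gaussian smoothing of the power spectrum via FFT convolution
    gy <- stats::dnorm(.centered_index(nr), sd = smoothing)
    gx <- stats::dnorm(.centered_index(nc), sd = smoothing)
    ker <- outer(gy / sum(gy), gx / sum(gx))
    P <- Re(stats::fft(stats::fft(P) * stats::fft(ker), inverse = TRUE)) /
      length(P)
    P <- pmax(P, 0)
  }
  pitch_mm <- pixel_pitch_um / 1000
  fy <- .centered_index(nr) / (nr * pitch_mm)
  fx <- .centered_index(nc) / (nc * pitch_mm)
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  nyq <- 1 / (2 * pitch_mm)
  nbins <- floor(min(nr, nc) / 2)
  df <- nyq / nbins
  bin <- pmin(nbins, ceiling(fr / df))
  keep <- fr > 0 & fr <= nyq
  pow <- vapply(split(P[keep], bin[keep]), mean, numeric(1))
  freq <- as.numeric(names(pow)) * df
  ord <- order(freq)
  pow <- pow[ord]; freq <- freq[ord]
  top <- freq >= 0.9 * nyq
  if (!any(top)) top <- freq >= stats::quantile(freq, 0.9)
  baseline <- stats::median(pow[top])
  ok <- pow >= 2 * baseline
  if (!any(ok)) {
    warning("no radial frequency clears twice the noise baseline; image looks signal-free")
    return(freq[1])
  }
  min(freq[max(which(ok))], nyq)
}

# FFT frequency index, centred: 0, 1, ..., n/2, -(n/2-1), ..., -1 (unshifted
# order matching R's fft layout).
.centered_index <- function(n) {
  half <- floor(n / 2)
  idx <- c(0:half, seq.int(-(n - half - 1), -1))
  idx[seq_len(n)]
}

#' Quality report for one image
#'
#' CNR, its sub-block standard error, and power-spectrum resolution.
#'
#' @param image Numeric matrix.
#' @param rois A [roi_set()].
#' @param pixel_pitch_um Pixel pitch in micrometres.
#' @param n_splits Blocks for [cnr_uncertainty()].
#' @param smoothing Power-spectrum smoothing parameter.
#' @return Object of class `quality_report`: list with `cnr`, `cnr_se`,
#'   `resolution_lp_mm`, `nyquist_lp_mm`, `pixel_pitch_um`.
#' @export
quality_report <- function(image, rois, pixel_pitch_um = 71, n_splits = 4L,
                           smoothing = 0.9) {
  structure(list(
    cnr = cnr(image, rois),
    cnr_se = cnr_uncertainty(image, rois, n_splits),
    resolution_lp_mm = resolution_power_spectrum(image, pixel_pitch_um,
                                                 smoothing),
    nyquist_lp_mm = 1000 / (2 * pixel_pitch_um),
    pixel_pitch_um = pixel_pitch_um), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> CNR %.2f +/- %.2f, resolution %.2f lp/mm (Nyquist %.2f)\n",
              x$cnr, x$cnr_se, x$resolution_lp_mm, x$nyquist_lp_mm))
  invisible(x)
}
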