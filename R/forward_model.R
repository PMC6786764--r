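# Radiograph synthesis: spectrum-weighted Beer-Lambert transmission on the
# detector grid, Poisson counting noise, dark-current and flat-field
# correction, and conversion to log-attenuation.

#' Radiograph container
#'
#' @param intensity Matrix of detected counts (or, after correction, relative
#'   intensity).
#' @param pixel_pitch_um Detector pixel pitch in micrometres (default 71).
#' @param spectrum The [make_spectrum()] used for acquisition (or `NULL`).
#' @param exposure_s Exposure time in seconds.
#' @param corrected Logical: has dark/flat correction been applied?
#' @param seed Poisson seed used, or `NULL` for a noiseless expectation.
#' @return Object of class `radiograph`.
#' @export
radiograph <- function(intensity, pixel_pitch_um = 71, spectrum = NULL,
                       exposure_s = NA_real_, corrected = FALSE, seed = NULL) {
  if (!is.matrix(intensity)) stop("intensity must be a matrix")
  if (pixel_pitch_um <= 0) stop("pixel pitch must be positive")
  structure(list(intensity = intensity, pixel_pitch_um = pixel_pitch_um,
                 spectrum = spectrum, exposure_s = exposure_s,
                 corrected = corrected, seed = seed),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %d x %d px @ %g um, exposure %g s, %s%s\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_pitch_um,
              x$exposure_s, if (x$corrected) "corrected" else "raw counts",
              if (is.null(x$seed)) " (noiseless)" else
                sprintf(" (Poisson seed %d)", x$seed)))
  invisible(x)
}

#' Registered low/high-energy radiograph pair
#'
#' @param low,high [radiograph()]s on the same grid with identical pitch.
#' @return Object of class `radiograph_pair`.
#' @export
radiograph_pair <- function(low, high) {
  stopifnot(inherits(low, "radiograph"), inherits(high, "radiograph"))
  if (!identical(dim(low$intensity), dim(high$intensity)))
    stop("pair members must share the same grid shape")
  if (low$pixel_pitch_um != high$pixel_pitch_um)
    stop("pair members must share the same pixel pitch")
  structure(list(low = low, high = high), class = "radiograph_pair")
}

#' Forward-project a phantom into a radiograph
#'
#' Expected counts per pixel are
#' `N(x, y) = exposure * flux_per_pixel * sum_E w(E) exp(-sum_m mu_m(E) t_m(x, y))`
#' with `flux_per_pixel = photons_per_second / beam_area * pitch^2 *
#' efficiency`. The beam is treated as parallel through the slab (the
#' source-detector distance vastly exceeds the phantom thickness). With
#' `seed = NULL` the noiseless expectation is returned; otherwise counts are
#' Poisson-sampled under that seed (the caller's RNG stream is preserved).
#'
#' @param phantom A `phantom_model`.
#' @param spectrum A [make_spectrum()] object.
#' @param flux A [beamline_flux()].
#' @param exposure_s Exposure time in seconds (> 0).
#' @param seed Integer Poisson seed, or `NULL` for the noiseless expectation.
#' @param tables Named list of [material_attenuation()] tables covering every
#'   material in the phantom across the spectrum span; defaults to the shipped
#'   tables.
#' @param efficiency Scalar detector efficiency in (0, 1].
#' @return A [radiograph()] of raw (uncorrected) counts.
#' @export
project <- function(phantom, spectrum, flux, exposure_s, seed = NULL,
                    tables = NULL, efficiency = 1) {
  stopifnot(inherits(phantom, "phantom_model"), inherits(spectrum, "spectrum"),
            inherits(flux, "beamline_flux"))
  if (exposure_s <= 0) stop("exposure must be positive")
  if (efficiency <= 0 || efficiency > 1) stop("efficiency must be in (0, 1]")
  mats <- names(phantom$thickness_maps)
  if (is.null(tables)) tables <- default_attenuation_tables(
    unique(c(mats, character(0))))
  missing <- setdiff(mats, names(tables))
  if (length(missing))
    stop("no attenuation table for material(s): ", paste(missing, collapse = ", "))
  nr <- phantom$extent_px[1]; nc <- phantom$extent_px[2]
  e <- spectrum$bin_energies; w <- spectrum$weights
  # attenuation coefficients per (energy bin, material)
  mu <- vapply(mats, function(m) mu_at(tables[[m]], e), numeric(length(e)))
  mu <- matrix(mu, nrow = length(e))
  trans <- matrix(0, nr, nc)
  for (k in seq_along(e)) {
    A <- matrix(0, nr, nc)
    for (j in seq_along(mats))
      A <- A + mu[k, j] * phantom$thickness_maps[[mats[j]]]
    trans <- trans + w[k] * exp(-A)
  }
  n0 <- exposure_s * flux$photons_per_second / flux$beam_area_cm2 *
    phantom$pixel_pitch_cm^2 * efficiency
  expected <- n0 * trans
  if (any(expected > .Machine$integer.max))
    stop("expected counts exceed the sampling guard; reduce flux or exposure")
  counts <- if (is.null(seed)) expected else
    .with_seed(seed, matrix(stats::rpois(length(expected), expected), nr, nc))
  radiograph(counts, pixel_pitch_um = phantom$pixel_pitch_cm * 1e4,
             spectrum = spectrum, exposure_s = exposure_s,
             corrected = FALSE, seed = seed)
}

#' Dark-current and flat-field correction
#'
#' `corrected = (raw - dark) / (flat - dark)`. With the study protocol the
#' flat is acquired through a 6 cm PMMA block, so downstream log-attenuation
#' is relative to that reference.
#'
#' @param raw,flat Raw and flat-field [radiograph()]s on the same grid.
#' @param dark Dark [radiograph()], a matrix, or a scalar offset (default 0).
#' @return A corrected [radiograph()] (`corrected = TRUE`).
#' @export
flat_dark_correct <- function(raw, flat, dark = 0) {
  stopifnot(inherits(raw, "radiograph"), inherits(flat, "radiograph"))
  dk <- if (inherits(dark, "radiograph")) dark$intensity else dark
  if (!identical(dim(raw$intensity), dim(flat$intensity)))
    stop("raw and flat grids differ")
  if (is.matrix(dk) && !identical(dim(dk), dim(raw$intensity)))
    stop("dark grid differs from raw")
  denom <- flat$intensity - dk
  nbad <- sum(denom <= 0)
  if (nbad > 0)
    stop(sprintf("flat minus dark is non-positive at %d pixel(s)", nbad))
  out <- (raw$intensity - dk) / denom
  radiograph(out, pixel_pitch_um = raw$pixel_pitch_um, spectrum = raw$spectrum,
             exposure_s = raw$exposure_s, corrected = TRUE, seed = raw$seed)
}

#' Log-attenuation image
#'
#' `A(x, y) = -ln(I/I0)` of a corrected radiograph: the measured attenuation
#' data consumed by the recombination step. Non-positive pixels (possible
#' under extreme noise) are masked, not silently propagated: the returned
#' matrix carries an attribute `mask` flagging them, their values are `NA`,
#' and a warning reports the count.
#'
#' @param corrected A corrected [radiograph()] or a plain matrix of relative
#'   intensities.
#' @return Matrix of log-attenuation values with attribute `mask` (logical
#'   matrix) when any pixel was masked.
#' @export
attenuation_image <- function(corrected) {
  x <- if (inherits(corrected, "radiograph")) corrected$intensity else corrected
  if (!is.matrix(x)) stop("expected a radiograph or matrix")
  bad <- !(x > 0)
  A <- matrix(NA_real_, nrow(x), ncol(x))
  A[!bad] <- -log(x[!bad])
  if (any(bad)) {
    warning(sprintf("%d non-positive pixel(s) masked in log-attenuation", sum(bad)))
    attr(A, "mask") <- bad
  }
  A
}

# TIFF storage: physical values are rescaled per page to [0, 1] and the
# offset/scale pair recorded in the JSON sidecar, so arbitrary-valued images
# (counts, log-attenuation, equivalent thickness) survive the round trip.
.tiff_pack <- function(pages) {
  scales <- lapply(pages, function(p) {
    off <- min(p); sc <- max(p) - off
    if (sc == 0) sc <- 1
    list(offset = off, scale = sc)
  })
  list(pages = Map(function(p, s) (p - s$offset) / s$scale, pages, scales),
       scales = scales)
}

.tiff_unpack <- function(pages, scales) {
  Map(function(p, s) p * s$scale + s$offset, pages, scales)
}

#' Write / read a radiograph as TIFF with a JSON sidecar
#'
#' Pixel values are rescaled to the unit range for storage (32-bit samples);
#' the offset/scale pair and the acquisition metadata (pitch, central energy,
#' exposure, seed, corrected flag) go to a JSON sidecar with the same stem,
#' from which [read_radiograph_tiff()] restores physical values.
#'
#' @param rad A [radiograph()].
#' @param path TIFF path.
#' @return `path` (write) or a `radiograph` (read).
#' @export
write_radiograph_tiff <- function(rad, path) {
  stopifnot(inherits(rad, "radiograph"))
  pk <- .tiff_pack(list(rad$intensity))
  tiff::writeTIFF(pk$pages[[1]], path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_pitch_um = rad$pixel_pitch_um,
         e_central_kev = if (!is.null(rad$spectrum)) rad$spectrum$E_central else NULL,
         exposure_s = rad$exposure_s, corrected = rad$corrected,
         seed = rad$seed, value_scaling = pk$scales[[1]]),
    sub("\\.tiff?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_radiograph_tiff
#' @export
read_radiograph_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side <- sub("\\.tiff?$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (!is.null(meta$value_scaling))
    img <- .tiff_unpack(list(img), list(meta$value_scaling))[[1]]
  radiograph(img,
             pixel_pitch_um = if (!is.null(meta$pixel_pitch_um))
               meta$pixel_pitch_um else 71,
             exposure_s = if (!is.null(meta$exposure_s))
               meta$exposure_s else NA_real_,
             corrected = isTRUE(meta$corrected),
             seed = if (!is.null(meta$seed)) meta$seed else NULL)
}
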