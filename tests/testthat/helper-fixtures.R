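# Shared fixtures: all test inputs are generated in code.

# Assemble a phantom_model directly from named thickness-map matrices.
phantom_from_maps <- function(maps, pixel_pitch_cm = 0.0071) {
  dims <- dim(maps[[1]])
  structure(list(pixel_pitch_cm = pixel_pitch_cm, extent_px = dims,
                 thickness_maps = maps, features = data.frame(),
                 config = NULL, seed = NULL),
            class = "phantom_model")
}

# Noiseless log-attenuation of a phantom at a delta spectrum, relative to the
# open beam (flat through nothing).
delta_attenuation <- function(phantom, E_kev, tables = NULL, flux = NULL) {
  if (is.null(flux)) flux <- beamline_flux(photons_per_second = 1e8,
                                           beam_area_cm2 = 1)
  spec <- make_spectrum(E_kev)
  raw <- project(phantom, spec, flux, exposure_s = 1, seed = NULL,
                 tables = tables)
  open <- slab_phantom("pmma", 0, extent_px = phantom$extent_px,
                       pixel_pitch_cm = phantom$pixel_pitch_cm)
  flat <- project(open, spec, flux, exposure_s = 1, seed = NULL,
                  tables = tables)
  attenuation_image(flat_dark_correct(raw, flat))
}

# Periodic Gaussian blur of a square matrix (FFT convolution), for building
# band-limited test images.
fft_blur <- function(img, sigma_px) {
  n <- nrow(img)
  idx <- c(0:floor(n / 2), seq.int(-(n - floor(n / 2) - 1), -1))
  g <- stats::dnorm(idx, sd = sigma_px)
  k <- outer(g, g)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(img) * stats::fft(k), inverse = TRUE)) / length(img)
}

# Small phantom + ROI layout used by the dose-ladder simulations: a reduced
# field of view holding a 0.5 cm x 0.8 cm iodine tube, no other features.
small_tube_config <- function(extent_px = c(160L, 240L)) {
  phantom_config(
    pixel_pitch_cm = 0.0071, extent_px = extent_px,
    iodine_tube = list(center_cm = c(1.2, 0.55), width_cm = 0.5,
                       height_cm = 0.8, path_cm = 1, concentration_mg_ml = 6),
    speck_groups = list(), masses = list(), fibers = list())
}

small_tube_rois <- function() {
  px <- function(cm) as.integer(round(cm / 0.0071))
  roi_set(roi(px(1.0), px(0.35), px(1.4), px(0.75)),
          roi(px(0.35), px(0.35), px(0.75), px(0.75)),
          roi(px(0.35), px(0.00), px(0.75), px(0.30)))
}
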