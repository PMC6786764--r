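test_that("an empty phantom transmits the full per-pixel fluence", {
  open <- slab_phantom("pmma", 0, extent_px = c(20L, 30L),
                       pixel_pitch_cm = 0.01)
  fl <- beamline_flux(photons_per_second = 1e8, beam_area_cm2 = 2)
  r <- project(open, make_spectrum(25), fl, exposure_s = 3)
  expect_true(all(r$intensity == 3 * 1e8 / 2 * 0.01^2))
})

test_that("a delta spectrum reproduces monochromatic Beer-Lambert exactly", {
  ph <- phantom_from_maps(list(iodine = matrix(0.1, 16, 16)))
  A <- delta_attenuation(ph, 25)
  expect_equal(max(abs(A - 6.8796)), 0, tolerance = 1e-12)
  # transmission relative to open beam is exp(-mu d)
  fl <- beamline_flux(photons_per_second = 1e8, beam_area_cm2 = 1)
  r <- project(ph, make_spectrum(25), fl, 1)
  open <- project(slab_phantom("pmma", 0, c(16L, 16L), 0.0071),
                  make_spectrum(25), fl, 1)
  expect_equal(r$intensity[1, 1] / open$intensity[1, 1], exp(-6.8796),
               tolerance = 1e-12)
})

test_that("noiseless projection is bit-exact repeatable; seeded noise is reproducible", {
  ph <- build_phantom(small_tube_config(c(160L, 220L)), seed = 1)
  fl <- beamline_flux()
  s <- make_spectrum(25, 0.89, 21L)
  expect_identical(project(ph, s, fl, 0.5)$intensity,
                   project(ph, s, fl, 0.5)$intensity)
  n1 <- project(ph, s, fl, 0.5, seed = 7)
  n2 <- project(ph, s, fl, 0.5, seed = 7)
  expect_identical(n1$intensity, n2$intensity)
  expect_false(identical(n1$intensity, project(ph, s, fl, 0.5, seed = 8)$intensity))
})

test_that("projection refuses a material without an attenuation table", {
  ph <- phantom_from_maps(list(unobtainium = matrix(1, 4, 4)))
  expect_error(project(ph, make_spectrum(25), beamline_flux(), 1,
                       tables = default_attenuation_tables()),
               "unobtainium")
})

test_that("adding thickness never increases expected counts", {
  set.seed(21)
  fl <- beamline_flux()
  s <- make_spectrum(25, 0.89, 11L)
  for (k in 1:5) {
    t1 <- matrix(runif(100, 0, 3), 10, 10)
    extra <- matrix(runif(100, 0, 0.5), 10, 10)
    p1 <- phantom_from_maps(list(breast = t1))
    p2 <- phantom_from_maps(list(breast = t1 + extra))
    expect_true(all(project(p2, s, fl, 1)$intensity <=
                    project(p1, s, fl, 1)$intensity))
  }
})

test_that("quasi-monochromatic attenuation stays within 0.5% of the monochromatic value", {
  ph <- phantom_from_maps(list(breast = matrix(4.2, 12, 12)))
  fl <- beamline_flux(photons_per_second = 1e8, beam_area_cm2 = 1)
  open <- slab_phantom("pmma", 0, c(12L, 12L), 0.0071)
  for (p in list(c(25, 0.89), c(35, 1.50))) {
    s <- make_spectrum(p[1], p[2], 51L)
    A_spec <- attenuation_image(flat_dark_correct(
      project(ph, s, fl, 1), project(open, s, fl, 1)))
    A_mono <- delta_attenuation(ph, p[1])
    expect_equal(A_spec[1, 1], A_mono[1, 1], tolerance = 5e-3)
  }
})

test_that("flat and dark corrections follow (raw - dark)/(flat - dark)", {
  mk <- function(m) radiograph(m, pixel_pitch_um = 71)
  raw <- mk(matrix(c(2, 4, 6, 8), 2))
  expect_true(all(flat_dark_correct(raw, raw)$intensity == 1))
  flat <- mk(matrix(1.5, 2, 2))
  out <- flat_dark_correct(raw, flat, dark = 0.5)
  expect_equal(out$intensity, raw$intensity - 0.5)
  expect_true(out$corrected)
  expect_error(flat_dark_correct(raw, mk(matrix(0.2, 2, 2)), dark = 0.5),
               "4 pixel")
  expect_error(flat_dark_correct(raw, mk(matrix(1, 3, 3))), "grids differ")
})

test_that("a slab attenuation-matched to the PMMA flat corrects to unity", {
  mu_b <- mu_at(std_attenuation("breast"), 25)
  mu_p <- mu_at(std_attenuation("pmma"), 25)
  t_match <- 6 * mu_p / mu_b
  ph <- phantom_from_maps(list(breast = matrix(t_match, 8, 8)))
  flat_ph <- slab_phantom("pmma", 6, c(8L, 8L), 0.0071)
  fl <- beamline_flux(photons_per_second = 1e8, beam_area_cm2 = 1)
  s <- make_spectrum(25)
  corr <- flat_dark_correct(project(ph, s, fl, 1), project(flat_ph, s, fl, 1))
  expect_equal(max(abs(corr$intensity - 1)), 0, tolerance = 1e-12)
})

test_that("log-attenuation inverts transmission and masks non-positive pixels", {
  expect_equal(attenuation_image(matrix(1, 3, 3)), matrix(0, 3, 3))
  expect_equal(attenuation_image(matrix(exp(-3), 2, 2)), matrix(3, 2, 2))
  bad <- matrix(c(1, 0.5, 0, -1), 2)
  expect_warning(A <- attenuation_image(bad), "2 non-positive")
  expect_equal(sum(is.na(A)), 2)
  expect_equal(attr(A, "mask"), bad <= 0)
})

test_that("Poisson noise on the log-attenuation follows 1/sqrt(I)", {
  open <- slab_phantom("pmma", 0, extent_px = c(100L, 100L),
                       pixel_pitch_cm = 0.0071)
  I <- 1e4
  fl <- beamline_flux(photons_per_second = I / 0.0071^2, beam_area_cm2 = 1)
  r <- project(open, make_spectrum(25), fl, 1, seed = 5)
  A <- attenuation_image(flat_dark_correct(r, radiograph(matrix(I, 100, 100))))
  expect_equal(stats::sd(A), 1 / sqrt(I), tolerance = 0.03)
})

test_that("radiographs round-trip through float TIFF with their sidecar", {
  r <- radiograph(matrix(runif(64, 0, 5), 8), pixel_pitch_um = 71,
                  exposure_s = 1.5, corrected = TRUE, seed = 3L)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_radiograph_tiff(r, path)
  r2 <- read_radiograph_tiff(path)
  expect_equal(r2$intensity, r$intensity, tolerance = 1e-6)
  expect_equal(r2$exposure_s, 1.5)
  expect_true(r2$corrected)
})
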