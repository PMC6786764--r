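test_that("an empty feature list yields only the uniform background slab", {
  cfg <- phantom_config(extent_px = c(60L, 80L), iodine_tube = NULL,
                        speck_groups = list(), masses = list(), fibers = list())
  ph <- build_phantom(cfg, seed = 3)
  expect_true(all(ph$thickness_maps$breast == cfg$slab_thickness_cm))
  expect_true(all(ph$thickness_maps$calcium == 0))
  expect_true(all(ph$thickness_maps$iodine == 0))
  expect_equal(nrow(ph$features), 0)
})

test_that("rendering is deterministic for a fixed seed", {
  cfg <- phantom_config(extent_px = c(120L, 160L),
                        iodine_tube = list(center_cm = c(0.6, 0.45),
                                           width_cm = 0.4, height_cm = 0.6,
                                           path_cm = 1, concentration_mg_ml = 6),
                        speck_groups = list(list(center_cm = c(0.3, 0.3),
                                                 diameter_cm = 0.03, n = 4L,
                                                 spread_cm = 0.08)),
                        masses = list(), fibers = list())
  a <- build_phantom(cfg, seed = 9)
  b <- build_phantom(cfg, seed = 9)
  expect_identical(a$thickness_maps, b$thickness_maps)
  c <- build_phantom(cfg, seed = 10)
  expect_false(identical(a$thickness_maps$calcium, c$thickness_maps$calcium))
})

test_that("a disc speck integrates to its analytic volume", {
  cfg <- phantom_config(extent_px = c(200L, 200L), iodine_tube = NULL,
                        masses = list(), fibers = list(),
                        speck_groups = list(list(center_cm = c(0.7, 0.7),
                                                 diameter_cm = 1.0, n = 1L,
                                                 spread_cm = 0,
                                                 thickness_cm = 0.02)))
  ph <- build_phantom(cfg, seed = 1)
  vol <- sum(ph$thickness_maps$calcium) * ph$pixel_pitch_cm^2
  expect_equal(vol, pi * 0.5^2 * 0.02, tolerance = 1e-6)
})

test_that("material volume is conserved under grid refinement within 1%", {
  mk <- function(pitch, ext) phantom_config(
    pixel_pitch_cm = pitch, extent_px = ext,
    iodine_tube = list(center_cm = c(3.35, 1.70), width_cm = 1, height_cm = 3,
                       path_cm = 1, concentration_mg_ml = 6),
    speck_groups = list(list(center_cm = c(1.0, 0.9), diameter_cm = 0.032,
                             n = 6L, spread_cm = 0.12)),
    masses = list(list(center_cm = c(1.0, 2.4), diameter_cm = 0.20)),
    fibers = list(list(center_cm = c(2.1, 2.55), length_cm = 1.0,
                       diameter_cm = 0.075, angle_deg = 45)))
  coarse <- build_phantom(mk(0.0142, c(240L, 320L)), seed = 5)
  fine <- build_phantom(mk(0.0071, c(480L, 640L)), seed = 5)
  vol <- function(ph, m) sum(ph$thickness_maps[[m]]) * ph$pixel_pitch_cm^2
  # breast: compare the excess over the uniform slab (masses + fibres)
  excess <- function(ph) vol(ph, "breast") -
    4.2 * prod(ph$extent_px) * ph$pixel_pitch_cm^2
  expect_equal(excess(coarse), excess(fine), tolerance = 0.01)
  for (m in c("calcium", "iodine", "water"))
    expect_equal(vol(coarse, m), vol(fine, m), tolerance = 0.01)
})

test_that("maps are non-negative and feature placement is validated", {
  ph <- build_phantom(phantom_config(), seed = 2)
  for (m in ph$thickness_maps) expect_true(all(m >= 0))
  expect_error(build_phantom(phantom_config(
    extent_px = c(100L, 100L),
    iodine_tube = list(center_cm = c(0.5, 0.5), width_cm = 1, height_cm = 3,
                       path_cm = 1, concentration_mg_ml = 6))),
    "outside")
  expect_error(build_phantom(phantom_config(
    iodine_tube = NULL, speck_groups = list(), fibers = list(),
    masses = list(list(center_cm = c(1, 1), diameter_cm = -0.1)))),
    "positive")
})

test_that("line integrals expose the ground-truth basis thickness maps", {
  cfg_no_tube <- phantom_config(extent_px = c(80L, 80L), iodine_tube = NULL,
                                speck_groups = list(), masses = list(),
                                fibers = list())
  li0 <- line_integrals(build_phantom(cfg_no_tube, seed = 1))
  expect_true(all(li0$d_I == 0))

  cfg <- phantom_config(extent_px = c(200L, 200L),
                        iodine_tube = list(center_cm = c(0.7, 0.7),
                                           width_cm = 0.4, height_cm = 0.6,
                                           path_cm = 1,
                                           concentration_mg_ml = 6),
                        speck_groups = list(list(center_cm = c(0.3, 0.3),
                                                 diameter_cm = 0.05, n = 1L,
                                                 spread_cm = 0)),
                        masses = list(), fibers = list())
  ph <- build_phantom(cfg, seed = 1)
  li <- line_integrals(ph)
  # tube interior: iodine-equivalent path of a 6 mg/ml, 1 cm solution column
  expect_equal(li$d_I[round(0.7 / 0.0071), round(0.7 / 0.0071)],
               0.006 / 4.93, tolerance = 1e-12)
  expect_equal(li$d_I[round(0.7 / 0.0071), round(0.7 / 0.0071)],
               1.217e-3, tolerance = 1e-3)
  # d_C over the speck equals the rendered calcium thickness
  expect_identical(li$d_C, ph$thickness_maps$calcium)
})

test_that("phantom maps export to multi-page float TIFF and read back", {
  cfg <- phantom_config(extent_px = c(64L, 64L),
                        iodine_tube = list(center_cm = c(0.22, 0.22),
                                           width_cm = 0.2, height_cm = 0.3,
                                           path_cm = 1, concentration_mg_ml = 6),
                        speck_groups = list(), masses = list(), fibers = list())
  ph <- build_phantom(cfg, seed = 1)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_phantom_tiff(ph, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_length(pages, length(ph$thickness_maps))
  meta <- jsonlite::read_json(sub("\\.tiff$", ".json", path),
                              simplifyVector = TRUE)
  restored <- pages[[1]] * meta$value_scaling$scale[1] +
    meta$value_scaling$offset[1]
  expect_equal(restored, ph$thickness_maps$breast, tolerance = 1e-6)
  expect_equal(meta$pixel_pitch_cm, ph$pixel_pitch_cm)
})
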