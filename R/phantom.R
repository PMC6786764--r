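# Digital twin of the modified mammographic accreditation phantom:
# per-material thickness maps (cm along the beam) on a lateral pixel grid.
#
# Coordinate convention: x runs along columns, y along rows, both in cm from
# the top-left corner; pixel (i, j) is centred at ((j-0.5)*pitch, (i-0.5)*pitch).

#' Phantom configuration
#'
#' Parameters of the synthetic accreditation phantom: a uniform 50/50
#' glandular/adipose slab containing calcium speck groups
#' (microcalcifications), lens-shaped tumour masses, nylon-like fibres, and a
#' rectangular iodine-solution insert mimicking an Eppendorf tube placed on
#' the phantom. Defaults follow the study conditions: 4.2 cm slab, 71 um
#' pixels, a 1 cm x 3 cm tube at 6 mg/ml, and feature-size ladders typical of
#' accreditation phantoms (specks 0.16-0.54 mm, masses 0.25-2.0 mm, fibres
#' 0.4-1.56 mm diameter).
#'
#' @param pixel_pitch_cm Lateral grid spacing in cm (default 71 um).
#' @param extent_px Grid dimensions `c(rows, cols)`.
#' @param slab_thickness_cm Uniform background slab thickness (cm of 50/50
#'   breast tissue along the beam).
#' @param iodine_tube List: `center_cm` (x, y), `width_cm`, `height_cm`
#'   (footprint), `path_cm` (internal solution path along the beam),
#'   `concentration_mg_ml`. `NULL` for no tube.
#' @param speck_groups List of groups, each a list with `center_cm`,
#'   `diameter_cm`, `n`, `spread_cm`, and optional `thickness_cm`
#'   (defaults to the diameter).
#' @param masses List of masses, each with `center_cm`, `diameter_cm`
#'   (sphere diameter; rendered as a spherical-cap excess of breast-equivalent
#'   thickness).
#' @param fibers List of fibres, each with `center_cm`, `length_cm`,
#'   `diameter_cm`, `angle_deg` (rendered as thin rotated rectangles of excess
#'   breast-equivalent thickness).
#' @param rho_iodine_g_cm3 Elemental iodine density used by [dilute_iodine()].
#'
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(pixel_pitch_cm = 0.0071,
                           extent_px = c(480L, 640L),
                           slab_thickness_cm = 4.2,
                           iodine_tube = list(center_cm = c(3.35, 1.70),
                                              width_cm = 1, height_cm = 3,
                                              path_cm = 1,
                                              concentration_mg_ml = 6),
                           speck_groups = list(list(center_cm = c(1.0, 0.9),
                                                    diameter_cm = 0.032,
                                                    n = 6L, spread_cm = 0.12)),
                           masses = list(list(center_cm = c(1.0, 2.4),
                                              diameter_cm = 0.20)),
                           fibers = list(list(center_cm = c(2.1, 2.55),
                                              length_cm = 1.0,
                                              diameter_cm = 0.075,
                                              angle_deg = 45)),
                           rho_iodine_g_cm3 = 4.93) {
  if (pixel_pitch_cm <= 0) stop("pixel pitch must be positive")
  extent_px <- as.integer(extent_px)
  if (length(extent_px) != 2L || any(extent_px < 1L))
    stop("extent_px must be two positive integers (rows, cols)")
  if (slab_thickness_cm <= 0) stop("slab thickness must be positive")
  structure(list(pixel_pitch_cm = pixel_pitch_cm, extent_px = extent_px,
                 slab_thickness_cm = slab_thickness_cm,
                 iodine_tube = iodine_tube, speck_groups = speck_groups,
                 masses = masses, fibers = fibers,
                 rho_iodine_g_cm3 = rho_iodine_g_cm3),
            class = "phantom_config")
}

#' Read a phantom configuration from YAML
#'
#' Top-level keys mirror the arguments of [phantom_config()].
#'
#' @param path YAML file.
#' @return A `phantom_config` object.
#' @export
read_phantom_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(phantom_config, cfg[intersect(names(cfg),
                                        names(formals(phantom_config)))])
}

# --- geometry helpers -------------------------------------------------------

# Area of the unit disc intersected with the quadrant {x <= X, y <= Y}.
.unit_disc_corner_area <- function(X, Y) {
  if (X <= -1 || Y <= -1) return(0)
  X <- min(X, 1); Y <- min(Y, 1)
  Sint <- function(x) (x * sqrt(pmax(0, 1 - x^2)) + asin(pmin(1, pmax(-1, x)))) / 2
  full <- function(x) x * sqrt(pmax(0, 1 - x^2)) + asin(pmin(1, pmax(-1, x))) + pi / 2
  if (Y >= 1) return(full(X))
  xc <- sqrt(max(0, 1 - Y^2))
  if (Y >= 0) {
    # |x| >= xc: full chord 2*s(x); |x| < xc: Y + s(x)
    a <- 0
    b1 <- min(X, -xc)
    a <- a + (full(b1) - full(-1))
    if (X > -xc) {
      b2 <- min(X, xc)
      a <- a + Y * (b2 + xc) + (Sint(b2) - Sint(-xc))
      if (X > xc) a <- a + (full(X) - full(xc))
    }
    a
  } else {
    # contribution only where s(x) > -Y, i.e. |x| < xc
    lo <- max(-xc, -1)
    hi <- min(X, xc)
    if (hi <= lo) return(0)
    Y * (hi - lo) + (Sint(hi) - Sint(lo))
  }
}

# Exact area of disc (centre cx, cy, radius r) within the axis-aligned pixel
# [x0, x1] x [y0, y1], as a fraction of the disc-free pixel area.
.disc_pixel_area <- function(cx, cy, r, x0, x1, y0, y1) {
  f <- function(X, Y) .unit_disc_corner_area((X - cx) / r, (Y - cy) / r)
  r^2 * (f(x1, y1) - f(x0, y1) - f(x1, y0) + f(x0, y0))
}

# Render a uniform-thickness disc into map (exact pixel coverage).
.add_disc <- function(map, pitch, cx, cy, r, thickness) {
  nr <- nrow(map); nc <- ncol(map)
  j0 <- max(1L, floor((cx - r) / pitch)); j1 <- min(nc, ceiling((cx + r) / pitch) + 1L)
  i0 <- max(1L, floor((cy - r) / pitch)); i1 <- min(nr, ceiling((cy + r) / pitch) + 1L)
  for (i in i0:i1) {
    y0 <- (i - 1) * pitch; y1 <- i * pitch
    for (j in j0:j1) {
      x0 <- (j - 1) * pitch; x1 <- j * pitch
      a <- .disc_pixel_area(cx, cy, r, x0, x1, y0, y1)
      if (a > 0) map[i, j] <- map[i, j] + thickness * a / pitch^2
    }
  }
  map
}

# Render an axis-aligned rectangle of uniform thickness (exact coverage).
.add_rect <- function(map, pitch, cx, cy, w, h, thickness) {
  nr <- nrow(map); nc <- ncol(map)
  xl <- cx - w / 2; xr <- cx + w / 2
  yl <- cy - h / 2; yr <- cy + h / 2
  jx <- seq_len(nc); iy <- seq_len(nr)
  covx <- pmax(0, pmin(xr, jx * pitch) - pmax(xl, (jx - 1) * pitch)) / pitch
  covy <- pmax(0, pmin(yr, iy * pitch) - pmax(yl, (iy - 1) * pitch)) / pitch
  map + thickness * outer(covy, covx)
}

# Supersampled rendering of a rotated rectangle of uniform thickness.
.add_rot_rect <- function(map, pitch, cx, cy, L, W, angle_deg, thickness, ss = 6L) {
  nr <- nrow(map); nc <- ncol(map)
  th <- angle_deg * pi / 180
  rad <- sqrt(L^2 + W^2) / 2
  j0 <- max(1L, floor((cx - rad) / pitch)); j1 <- min(nc, ceiling((cx + rad) / pitch) + 1L)
  i0 <- max(1L, floor((cy - rad) / pitch)); i1 <- min(nr, ceiling((cy + rad) / pitch) + 1L)
  off <- (seq_len(ss) - 0.5) / ss
  xs <- as.vector(outer(((j0:j1) - 1) * pitch, off * pitch, `+`))
  ys <- as.vector(outer(((i0:i1) - 1) * pitch, off * pitch, `+`))
  u <- outer(ys - cy, xs - cx, function(dy, dx) cos(th) * dx + sin(th) * dy)
  v <- outer(ys - cy, xs - cx, function(dy, dx) -sin(th) * dx + cos(th) * dy)
  inside <- (abs(u) <= L / 2) & (abs(v) <= W / 2)
  nyi <- length(i0:i1); nxi <- length(j0:j1)
  dim(inside) <- c(nyi, ss, nxi, ss)
  cov <- apply(inside, c(1, 3), mean)
  map[i0:i1, j0:j1] <- map[i0:i1, j0:j1] + thickness * cov
  map
}

# Supersampled spherical-cap (lens) excess thickness: 2*sqrt(R^2 - rho^2).
.add_lens <- function(map, pitch, cx, cy, R, ss = 4L) {
  nr <- nrow(map); nc <- ncol(map)
  j0 <- max(1L, floor((cx - R) / pitch)); j1 <- min(nc, ceiling((cx + R) / pitch) + 1L)
  i0 <- max(1L, floor((cy - R) / pitch)); i1 <- min(nr, ceiling((cy + R) / pitch) + 1L)
  off <- (seq_len(ss) - 0.5) / ss
  xs <- as.vector(outer(((j0:j1) - 1) * pitch, off * pitch, `+`))
  ys <- as.vector(outer(((i0:i1) - 1) * pitch, off * pitch, `+`))
  t <- outer(ys - cy, xs - cx,
             function(dy, dx) 2 * sqrt(pmax(0, R^2 - dx^2 - dy^2)))
  nyi <- length(i0:i1); nxi <- length(j0:j1)
  dim(t) <- c(nyi, ss, nxi, ss)
  map[i0:i1, j0:j1] <- map[i0:i1, j0:j1] + apply(t, c(1, 3), mean)
  map
}

# --- phantom construction ---------------------------------------------------

.check_inside <- function(kind, cx, cy, halfx, halfy, fov) {
  if (cx - halfx < 0 || cx + halfx > fov[1] || cy - halfy < 0 || cy + halfy > fov[2])
    stop(sprintf("%s at (%.3g, %.3g) cm extends outside the %g x %g cm field of view",
                 kind, cx, cy, fov[1], fov[2]))
}

#' Build the synthetic accreditation phantom
#'
#' Renders the configured features into per-material thickness maps. Speck and
#' tube footprints use exact pixel coverage; masses and fibres are
#' supersampled, so total material volume is conserved under grid refinement.
#' Speck positions within a group are jittered deterministically from `seed`.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed controlling speck placement jitter.
#' @return An object of class `phantom_model` with fields `pixel_pitch_cm`,
#'   `extent_px`, `thickness_maps` (named list of matrices, cm of material),
#'   and `features` (a data frame registry).
#' @export
build_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  pitch <- config$pixel_pitch_cm
  nr <- config$extent_px[1]; nc <- config$extent_px[2]
  fov <- c(nc * pitch, nr * pitch)  # (x, y) extent in cm
  zero <- matrix(0, nr, nc)
  maps <- list(breast = zero + config$slab_thickness_cm,
               calcium = zero, iodine = zero, water = zero)
  feats <- list()
  for (g in config$speck_groups) {
    d <- g$diameter_cm
    if (d <= 0 || is.null(g$n) || g$n < 1) stop("speck group needs positive diameter and n")
    thick <- if (!is.null(g$thickness_cm)) g$thickness_cm else d
    ang <- 2 * pi * (seq_len(g$n) - 1) / g$n
    jit <- .with_seed(seed + length(feats),
                      matrix(stats::rnorm(2 * g$n, sd = g$spread_cm / 8), ncol = 2))
    px <- g$center_cm[1] + g$spread_cm * cos(ang) + jit[, 1]
    py <- g$center_cm[2] + g$spread_cm * sin(ang) + jit[, 2]
    for (k in seq_len(g$n)) {
      .check_inside("speck", px[k], py[k], d / 2, d / 2, fov)
      maps$calcium <- .add_disc(maps$calcium, pitch, px[k], py[k], d / 2, thick)
      feats[[length(feats) + 1L]] <-
        data.frame(kind = "speck_group", x_cm = px[k], y_cm = py[k],
                   size_cm = d, thickness_cm = thick, angle_deg = 0,
                   material = "calcium")
    }
  }
  for (m in config$masses) {
    if (m$diameter_cm <= 0) stop("mass diameter must be positive")
    R <- m$diameter_cm / 2
    .check_inside("mass", m$center_cm[1], m$center_cm[2], R, R, fov)
    if (m$diameter_cm > config$slab_thickness_cm)
      stop("mass thicker than the background slab")
    maps$breast <- .add_lens(maps$breast, pitch, m$center_cm[1], m$center_cm[2], R)
    feats[[length(feats) + 1L]] <-
      data.frame(kind = "mass", x_cm = m$center_cm[1], y_cm = m$center_cm[2],
                 size_cm = m$diameter_cm, thickness_cm = m$diameter_cm,
                 angle_deg = 0, material = "breast")
  }
  for (f in config$fibers) {
    if (f$length_cm <= 0 || f$diameter_cm <= 0) stop("fibre sizes must be positive")
    rad <- sqrt(f$length_cm^2 + f$diameter_cm^2) / 2
    .check_inside("fiber", f$center_cm[1], f$center_cm[2], rad, rad, fov)
    maps$breast <- .add_rot_rect(maps$breast, pitch, f$center_cm[1], f$center_cm[2],
                                 f$length_cm, f$diameter_cm, f$angle_deg,
                                 f$diameter_cm)
    feats[[length(feats) + 1L]] <-
      data.frame(kind = "fiber", x_cm = f$center_cm[1], y_cm = f$center_cm[2],
                 size_cm = f$length_cm, thickness_cm = f$diameter_cm,
                 angle_deg = f$angle_deg, material = "breast")
  }
  tube <- config$iodine_tube
  if (!is.null(tube)) {
    if (tube$width_cm <= 0 || tube$height_cm <= 0 || tube$path_cm <= 0)
      stop("iodine tube sizes must be positive")
    .check_inside("iodine_tube", tube$center_cm[1], tube$center_cm[2],
                  tube$width_cm / 2, tube$height_cm / 2, fov)
    dI <- dilute_iodine(tube$concentration_mg_ml, config$rho_iodine_g_cm3) *
      tube$path_cm
    maps$iodine <- .add_rect(maps$iodine, pitch, tube$center_cm[1],
                             tube$center_cm[2], tube$width_cm, tube$height_cm, dI)
    maps$water <- .add_rect(maps$water, pitch, tube$center_cm[1],
                            tube$center_cm[2], tube$width_cm, tube$height_cm,
                            tube$path_cm - dI)
    feats[[length(feats) + 1L]] <-
      data.frame(kind = "iodine_tube", x_cm = tube$center_cm[1],
                 y_cm = tube$center_cm[2], size_cm = tube$width_cm,
                 thickness_cm = dI, angle_deg = 0, material = "iodine")
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(kind = character(), x_cm = numeric(), y_cm = numeric(),
               size_cm = numeric(), thickness_cm = numeric(),
               angle_deg = numeric(), material = character())
  if (any(vapply(maps, function(m) any(m < 0), logical(1))))
    stop("internal error: negative thickness rendered")
  structure(list(pixel_pitch_cm = pitch, extent_px = c(nr, nc),
                 thickness_maps = maps, features = features, config = config,
                 seed = seed),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("<phantom_model> %d x %d px @ %.1f um, materials: %s; %d features\n",
              x$extent_px[1], x$extent_px[2], x$pixel_pitch_cm * 1e4,
              paste(names(x$thickness_maps), collapse = ", "),
              nrow(x$features)))
  invisible(x)
}

#' Ground-truth basis-material line integrals
#'
#' Returns the phantom's iodine-equivalent and calcium-equivalent thickness
#' maps: the recovery targets for [material_decompose()].
#'
#' @param phantom A [build_phantom()] result.
#' @param basis Unused except to document against which basis the equivalent
#'   thicknesses are expressed (pure-element path lengths).
#' @return List with matrices `d_I` and `d_C` (cm).
#' @export
line_integrals <- function(phantom, basis = decomposition_basis()) {
  stopifnot(inherits(phantom, "phantom_model"))
  zero <- matrix(0, phantom$extent_px[1], phantom$extent_px[2])
  d_I <- if (!is.null(phantom$thickness_maps$iodine))
    phantom$thickness_maps$iodine else zero
  d_C <- if (!is.null(phantom$thickness_maps$calcium))
    phantom$thickness_maps$calcium else zero
  list(d_I = d_I, d_C = d_C)
}

#' Uniform reference slab phantom
#'
#' A single-material slab on a given grid; used for the 6 cm PMMA flat-field
#' reference and for open-beam (zero-thickness) projections.
#'
#' @param material Material name of the slab.
#' @param thickness_cm Slab thickness (0 for open beam).
#' @param extent_px Grid dimensions `c(rows, cols)`.
#' @param pixel_pitch_cm Grid spacing in cm.
#' @return A `phantom_model`.
#' @export
slab_phantom <- function(material = "pmma", thickness_cm = 6,
                         extent_px = c(480L, 640L), pixel_pitch_cm = 0.0071) {
  if (thickness_cm < 0) stop("slab thickness must be non-negative")
  maps <- stats::setNames(
    list(matrix(thickness_cm, extent_px[1], extent_px[2])), material)
  if (thickness_cm == 0) maps <- list()
  structure(list(pixel_pitch_cm = pixel_pitch_cm,
                 extent_px = as.integer(extent_px),
                 thickness_maps = maps,
                 features = data.frame(), config = NULL, seed = NULL),
            class = "phantom_model")
}

#' Export phantom thickness maps as multi-page TIFF
#'
#' One 32-bit page per material, rescaled to the unit range for storage; the
#' pixel pitch, material order and per-page offset/scale pairs are recorded
#' in a JSON sidecar next to the TIFF, from which physical thicknesses (cm)
#' can be restored.
#'
#' @param phantom A `phantom_model`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_phantom_tiff <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_model"))
  pk <- .tiff_pack(phantom$thickness_maps)
  tiff::writeTIFF(unname(pk$pages), path, bits.per.sample = 32L,
                  reduce = FALSE)
  side <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(
    list(pixel_pitch_cm = phantom$pixel_pitch_cm,
         materials = names(phantom$thickness_maps),
         value_scaling = unname(pk$scales),
         extent_px = phantom$extent_px, seed = phantom$seed),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
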