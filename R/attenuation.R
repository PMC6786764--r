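# Material attenuation tables, the photoelectric E^-3 scaling law, and the
# fixed iodine/calcium decomposition basis.

#' Material attenuation table
#'
#' Holds linear attenuation coefficients of one material on a strictly
#' increasing photon-energy grid. Values may be supplied directly in 1/cm, or
#' as mass attenuation coefficients (cm^2/g) together with a density (g/cm^3)
#' from which linear values are derived.
#'
#' @param material_name Label, e.g. `"iodine"`.
#' @param energies Strictly increasing energy grid in keV.
#' @param mu_per_cm Linear attenuation coefficients in 1/cm (all > 0).
#' @param mass_atten_cm2_g Mass attenuation coefficients in cm^2/g
#'   (alternative to `mu_per_cm`; requires `density_g_cm3`).
#' @param density_g_cm3 Material density in g/cm^3.
#'
#' @return An object of class `material_attenuation` with fields
#'   `material_name`, `energies`, `mu_linear`.
#' @seealso [mu_at()], [read_attenuation_table()], [std_attenuation()]
#' @export
material_attenuation <- function(material_name, energies, mu_per_cm = NULL,
                                 mass_atten_cm2_g = NULL, density_g_cm3 = NULL) {
  if (is.null(mu_per_cm)) {
    if (is.null(mass_atten_cm2_g) || is.null(density_g_cm3))
      stop("supply either mu_per_cm, or mass_atten_cm2_g plus density_g_cm3")
    mu_per_cm <- mass_atten_cm2_g * density_g_cm3
  }
  energies <- as.numeric(energies)
  mu_per_cm <- as.numeric(mu_per_cm)
  if (length(energies) != length(mu_per_cm) || length(energies) < 1L)
    stop("energies and attenuation values must have equal positive length")
  if (any(diff(energies) <= 0))
    stop("energy grid must be strictly increasing")
  if (any(mu_per_cm <= 0) || any(!is.finite(mu_per_cm)))
    stop("all attenuation coefficients must be positive and finite")
  structure(
    list(material_name = as.character(material_name),
         energies = energies, mu_linear = mu_per_cm),
    class = "material_attenuation")
}

#' @export
print.material_attenuation <- function(x, ...) {
  cat(sprintf("<material_attenuation> %s: %d grid points, %.4g-%.4g keV\n",
              x$material_name, length(x$energies),
              min(x$energies), max(x$energies)))
  invisible(x)
}

#' Interpolate a linear attenuation coefficient
#'
#' Log-log linear interpolation between the bracketing grid points (attenuation
#' is near power-law in energy between absorption edges). Queries that hit a
#' grid point return the stored value exactly. Edges such as the iodine K edge
#' are represented in the shipped tables by two grid points a few eV apart, so
#' interpolation never bridges the discontinuity except inside that sliver.
#'
#' @param material A [material_attenuation()] table.
#' @param E Energy (keV), scalar or vector; must lie within the table's span.
#' @return Linear attenuation coefficient(s) in 1/cm.
#' @export
mu_at <- function(material, E) {
  stopifnot(inherits(material, "material_attenuation"))
  E <- as.numeric(E)
  lo <- min(material$energies); hi <- max(material$energies)
  if (any(!is.finite(E)) || any(E < lo) || any(E > hi))
    stop(sprintf("energy outside the %s table span [%g, %g] keV",
                 material$material_name, lo, hi))
  out <- exp(stats::approx(log(material$energies), log(material$mu_linear),
                           xout = log(E), ties = "ordered")$y)
  hit <- match(E, material$energies)
  idx <- which(!is.na(hit))
  if (length(idx)) out[idx] <- material$mu_linear[hit[idx]]
  out
}

#' Photoelectric 1/E^3 energy scaling
#'
#' Scales an attenuation coefficient between energies under the photoelectric
#' approximation mu proportional to 1/E^3, the relation behind the empirical
#' K-edge subtraction energy correction.
#'
#' @param mu_ref Attenuation at `E_ref` (1/cm), > 0.
#' @param E_ref,E Reference and target energies in keV, > 0.
#' @return `mu_ref * (E_ref / E)^3`.
#' @export
photoelectric_scale <- function(mu_ref, E_ref, E) {
  if (any(mu_ref <= 0) || any(E_ref <= 0) || any(E <= 0))
    stop("photoelectric_scale requires strictly positive inputs")
  mu_ref * (E_ref / E)^3
}

#' Iodine-equivalent thickness of a dilute iodine solution
#'
#' Converts an iodine concentration to the pure-iodine-equivalent path length
#' per cm of solution: `concentration[g/cm^3] / rho_iodine`. The solvent
#' (water) contribution of the solution is modelled separately in the forward
#' model.
#'
#' @param concentration_mg_ml Iodine concentration in mg/ml (>= 0);
#'   the clinical value used for the contrast insert is 6 mg/ml.
#' @param rho_iodine Density of elemental iodine in g/cm^3 (default 4.93).
#' @return Iodine-equivalent thickness factor (cm of iodine per cm of solution).
#' @export
dilute_iodine <- function(concentration_mg_ml, rho_iodine = 4.93) {
  if (any(concentration_mg_ml < 0)) stop("concentration must be non-negative")
  if (rho_iodine <= 0) stop("rho_iodine must be positive")
  (concentration_mg_ml / 1000) / rho_iodine
}

#' Two-material decomposition basis
#'
#' Linear attenuation coefficients of the two basis materials (iodine and
#' calcium) at the low and high beam energies. Defaults are the literature
#' values for elemental iodine and calcium at 25/35 keV used throughout this
#' package; equivalent thicknesses recovered against this basis are therefore
#' pure-element-equivalent path lengths in cm.
#'
#' @param mu_I_low,mu_I_high Iodine attenuation at `E_low`/`E_high` (1/cm).
#' @param mu_C_low,mu_C_high Calcium attenuation at `E_low`/`E_high` (1/cm).
#' @param E_low,E_high Beam energies in keV.
#' @return Object of class `decomposition_basis` with a `det` field
#'   (`mu_I_low*mu_C_high - mu_I_high*mu_C_low`, must be nonzero).
#' @export
decomposition_basis <- function(mu_I_low = 68.796, mu_I_high = 154.109,
                                mu_C_low = 10.650, mu_C_high = 4.097,
                                E_low = 25, E_high = 35) {
  det <- mu_I_low * mu_C_high - mu_I_high * mu_C_low
  if (!is.finite(det) || det == 0)
    stop("decomposition basis is singular (zero determinant)")
  structure(
    list(mu_I_low = mu_I_low, mu_I_high = mu_I_high,
         mu_C_low = mu_C_low, mu_C_high = mu_C_high,
         E_low = E_low, E_high = E_high, det = det),
    class = "decomposition_basis")
}

#' @export
print.decomposition_basis <- function(x, ...) {
  cat(sprintf(paste0("<decomposition_basis> %g/%g keV\n",
                     "  mu_I: %.3f / %.3f 1/cm\n  mu_C: %.3f / %.3f 1/cm\n",
                     "  det : %.2f 1/cm^2\n"),
              x$E_low, x$E_high, x$mu_I_low, x$mu_I_high,
              x$mu_C_low, x$mu_C_high, x$det))
  invisible(x)
}

#' Read an attenuation table from CSV
#'
#' Expected columns: `energy_keV` and either `mu_per_cm` or
#' `mass_atten_cm2_g`. In the latter case a comment line
#' `# density_g_cm3: <value>` must be present. Lines starting with `#` are
#' treated as comments; a `# material: <name>` line overrides the default
#' material name (the file stem).
#'
#' @param path CSV file path.
#' @return A [material_attenuation()] object.
#' @export
read_attenuation_table <- function(path) {
  header <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  meta <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "\\s*:"), header, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^#\\s*", key, "\\s*:\\s*"), "", ln[[1]])
  }
  df <- utils::read.csv(path, comment.char = "#")
  name <- meta("material")
  if (is.null(name)) name <- sub("\\.csv$", "", basename(path))
  if ("mu_per_cm" %in% names(df)) {
    material_attenuation(name, df$energy_keV, mu_per_cm = df$mu_per_cm)
  } else if ("mass_atten_cm2_g" %in% names(df)) {
    dens <- meta("density_g_cm3")
    if (is.null(dens)) stop("mass attenuation table needs a '# density_g_cm3:' line")
    material_attenuation(name, df$energy_keV,
                         mass_atten_cm2_g = df$mass_atten_cm2_g,
                         density_g_cm3 = as.numeric(dens))
  } else {
    stop("attenuation CSV needs a mu_per_cm or mass_atten_cm2_g column")
  }
}

#' Shipped attenuation table for a standard material
#'
#' Loads one of the package's attenuation fixtures (15-40 keV):
#' `"iodine"`, `"calcium"`, `"breast"` (50/50 glandular/adipose), `"pmma"`,
#' `"water"`. The iodine table carries the K-edge discontinuity at 33.17 keV
#' as two grid points 2 eV apart.
#'
#' @param material Material name.
#' @return A [material_attenuation()] object.
#' @export
std_attenuation <- function(material = c("iodine", "calcium", "breast",
                                         "pmma", "water")) {
  material <- match.arg(material)
  path <- system.file("extdata", paste0("mu_", material, ".csv"),
                      package = "cesmsim", mustWork = TRUE)
  read_attenuation_table(path)
}

#' Default attenuation tables keyed by material name
#'
#' @param materials Character vector of material names understood by
#'   [std_attenuation()].
#' @return Named list of [material_attenuation()] tables.
#' @export
default_attenuation_tables <- function(materials = c("breast", "calcium",
                                                     "iodine", "water", "pmma")) {
  stats::setNames(lapply(materials, std_attenuation), materials)
}
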