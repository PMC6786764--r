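# Air kerma per energy bin and mean glandular dose (MGD) for an acquisition.

# Exposure-to-air-kerma conversion: 0.114 R of exposure per mGy of air kerma.
.ROENTGEN_PER_MGY <- 0.114

# keV per gram corresponding to 1 mGy (1e-3 J/kg / 1.602176634e-16 J/keV / 1e3 g/kg)
.KEV_PER_G_PER_MGY <- 1e-3 / 1.602176634e-16 / 1e3

#' Exposure/air-kerma conversion constant
#'
#' Returns 0.114 R/mGy, the constant linking air kerma to exposure in the MGD
#' formula `MGD = sum_E K(E) * 0.114 * DgN(E)`. Stored in exactly one place;
#' its reciprocal (about 8.77 mGy/R) converts exposure back to air kerma.
#'
#' @return 0.114 (R per mGy).
#' @export
roentgen_per_mgy <- function() .ROENTGEN_PER_MGY

#' Read an air mass-energy-absorption table
#'
#' CSV with columns `energy_keV, muen_cm2_g`; `#` comment lines allowed.
#' With `path = NULL` the shipped table (15-40 keV) is used.
#'
#' @param path CSV path or `NULL`.
#' @return Data frame with `energy_keV`, `muen_cm2_g`.
#' @export
read_air_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "air_muen.csv", package = "cesmsim",
                        mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("energy_keV", "muen_cm2_g") %in% names(df)))
  if (any(diff(df$energy_keV) <= 0)) stop("air table grid must be increasing")
  df
}

#' Read a DgN coefficient table
#'
#' Monoenergetic normalized glandular dose coefficients (mGy/R) on an energy
#' grid, for one breast thickness and glandularity (stored as `#` header
#' lines). With `path = NULL` the shipped synthetic stand-in for a 4.2 cm,
#' 50% glandularity breast is used; supply a literature table for
#' quantitative dosimetry.
#'
#' @param path CSV path or `NULL`.
#' @return Object of class `dgn_table` with fields `energies`, `dgn`,
#'   `breast_thickness_cm`, `glandularity`.
#' @export
read_dgn_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dgn_50glandular_42mm_synthetic.csv",
                        package = "cesmsim", mustWork = TRUE)
  hdr <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  val <- function(key, default) {
    ln <- grep(paste0("^#\\s*", key), hdr, value = TRUE)
    if (!length(ln)) return(default)
    as.numeric(sub(".*:\\s*", "", ln[[1]]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  dgn_table(df$energy_keV, df$dgn_mgy_per_r,
            breast_thickness_cm = val("breast_thickness_cm", NA_real_),
            glandularity = val("glandularity", 0.5))
}

#' DgN coefficient table constructor
#'
#' @param energies Increasing energy grid in keV.
#' @param dgn Coefficients in mGy/R (all > 0).
#' @param breast_thickness_cm Compressed breast thickness the table refers to.
#' @param glandularity Glandular fraction (default 0.5).
#' @return Object of class `dgn_table`.
#' @export
dgn_table <- function(energies, dgn, breast_thickness_cm = NA_real_,
                      glandularity = 0.5) {
  if (any(diff(energies) <= 0)) stop("DgN energy grid must be strictly increasing")
  if (any(dgn <= 0)) stop("DgN coefficients must be positive")
  structure(list(energies = as.numeric(energies), dgn = as.numeric(dgn),
                 breast_thickness_cm = breast_thickness_cm,
                 glandularity = glandularity),
            class = "dgn_table")
}

#' Air kerma per energy bin
#'
#' `K(E) = E * Phi(E) * (muen/rho)_air(E)`, with `Phi(E)` the photon fluence
#' per area in the bin (`weights * photons_per_second * exposure /
#' beam_area`). The keV cm^-2 (cm^2/g) product is converted to mGy explicitly
#' (1 mGy corresponds to 6.2415e9 keV per gram).
#'
#' @param spectrum A [make_spectrum()] object.
#' @param flux A [beamline_flux()].
#' @param exposure_s Exposure time in seconds (>= 0).
#' @param air_table Air mass-energy-absorption table ([read_air_table()]
#'   format); must cover the spectrum span.
#' @return Object of class `kerma_per_bin`: data frame with `energy_keV`,
#'   `kerma_mGy`.
#' @export
air_kerma <- function(spectrum, flux, exposure_s, air_table = read_air_table()) {
  stopifnot(inherits(spectrum, "spectrum"), inherits(flux, "beamline_flux"))
  if (exposure_s < 0) stop("exposure must be non-negative")
  e <- spectrum$bin_energies
  if (min(e) < min(air_table$energy_keV) || max(e) > max(air_table$energy_keV))
    stop(sprintf("air table covers [%g, %g] keV but spectrum spans [%g, %g]",
                 min(air_table$energy_keV), max(air_table$energy_keV),
                 min(e), max(e)))
  muen <- exp(stats::approx(log(air_table$energy_keV), log(air_table$muen_cm2_g),
                            xout = log(e), ties = "ordered")$y)
  hit <- match(e, air_table$energy_keV)
  muen[!is.na(hit)] <- air_table$muen_cm2_g[hit[!is.na(hit)]]
  fluence <- spectrum$weights * flux$photons_per_second * exposure_s /
    flux$beam_area_cm2
  k <- e * fluence * muen / .KEV_PER_G_PER_MGY
  structure(data.frame(energy_keV = e, kerma_mGy = k), class = c("kerma_per_bin",
                                                                "data.frame"))
}

#' Mean glandular dose from per-bin air kerma
#'
#' `MGD = sum_E K(E) * 0.114 * DgN(E)`, with DgN interpolated linearly in
#' energy.
#'
#' @param kerma_per_bin An [air_kerma()] result (or data frame with
#'   `energy_keV`, `kerma_mGy`).
#' @param dgn A [dgn_table()].
#' @return MGD in mGy (scalar).
#' @export
mgd <- function(kerma_per_bin, dgn = read_dgn_table()) {
  stopifnot(inherits(dgn, "dgn_table"))
  e <- kerma_per_bin$energy_keV
  k <- kerma_per_bin$kerma_mGy
  nz <- k > 0
  if (any(nz) && (min(e[nz]) < min(dgn$energies) || max(e[nz]) > max(dgn$energies)))
    stop(sprintf("DgN table covers [%g, %g] keV but kerma bins span [%g, %g]",
                 min(dgn$energies), max(dgn$energies), min(e[nz]), max(e[nz])))
  d <- stats::approx(dgn$energies, dgn$dgn, xout = e, ties = "ordered",
                     rule = 1)$y
  d[!nz & is.na(d)] <- 0  # bins with zero kerma may fall outside the table
  sum(k * .ROENTGEN_PER_MGY * d)
}

#' Dose report for one acquisition
#'
#' Convenience wrapper: air kerma and MGD for a spectrum/flux/exposure triple.
#'
#' @inheritParams air_kerma
#' @param dgn A [dgn_table()].
#' @return Object of class `dose_report`: list with `kerma_per_bin`,
#'   `mgd_mGy`, `E_central_keV`, `exposure_s`.
#' @export
dose_report <- function(spectrum, flux, exposure_s,
                        air_table = read_air_table(), dgn = read_dgn_table()) {
  k <- air_kerma(spectrum, flux, exposure_s, air_table)
  structure(list(kerma_per_bin = k, mgd_mGy = mgd(k, dgn),
                 E_central_keV = spectrum$E_central, exposure_s = exposure_s),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> %g keV, %g s: air kerma %.4g mGy, MGD %.4g mGy\n",
              x$E_central_keV, x$exposure_s, sum(x$kerma_per_bin$kerma_mGy),
              x$mgd_mGy))
  invisible(x)
}
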