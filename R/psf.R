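# Two-photon point-spread-function size model.
#
# The excitation volume is the squared intensity of a focused Gaussian beam.
# The 1/e radii of the two-photon (intensity-squared) volume follow the
# standard Gaussian-focus closed forms, with a low/high-N.A. branch switch at
# N.A. 0.7 for the lateral width; FWHM = 2*sqrt(ln 2) times the 1/e radius.

#' Predicted two-photon PSF FWHM from the effective N.A.
#'
#' @param effective_na Effective excitation numerical aperture (0 <
#'   `effective_na` < `immersion_index`).
#' @param wavelength_nm Vacuum wavelength, nm.
#' @param immersion_index Immersion refractive index (water: 1.33).
#' @return An object of class `ntc_psf`: list with `lateral_fwhm_um` and
#'   `axial_fwhm_um`.
#' @export
psf_fwhm <- function(effective_na, wavelength_nm = 927,
                     immersion_index = 1.33) {
  stopifnot(wavelength_nm > 0)
  if (effective_na <= 0) stop("effective_na must be > 0")
  if (effective_na >= immersion_index)
    stop("effective_na >= immersion_index: evanescent regime not modelled")
  lam_um <- wavelength_nm * 1e-3
  n <- immersion_index
  na <- effective_na
  w_xy <- if (na <= 0.7) {
    0.320 * lam_um / (sqrt(2) * na)
  } else {
    0.325 * lam_um / (sqrt(2) * na^0.91)
  }
  w_z <- 0.532 * lam_um / sqrt(2) / (n - sqrt(n^2 - na^2))
  k <- 2 * sqrt(log(2))
  structure(list(lateral_fwhm_um = k * w_xy,
                 axial_fwhm_um = k * w_z,
                 effective_na = na,
                 wavelength_nm = wavelength_nm,
                 immersion_index = n), class = "ntc_psf")
}

#' @export
print.ntc_psf <- function(x, ...) {
  cat(sprintf("<ntc_psf> lateral %.3f um, axial %.3f um (N.A. %.3f, %g nm)\n",
              x$lateral_fwhm_um, x$axial_fwhm_um, x$effective_na,
              x$wavelength_nm))
  invisible(x)
}

#' Conversion between Gaussian sigma and FWHM
#'
#' @param sigma Standard deviation(s).
#' @return FWHM, `2 * sqrt(2 * log(2)) * sigma`.
#' @export
sigma_to_fwhm <- function(sigma) 2 * sqrt(2 * log(2)) * sigma

#' @rdname sigma_to_fwhm
#' @param fwhm Full width(s) at half maximum.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Model-predicted PSF of a configuration
#'
#' Convenience wrapper: [effective_na()] then [psf_fwhm()].
#'
#' @param config An [optical_config()].
#' @param etl_power_dpt ETL power, diopters.
#' @return An `ntc_psf` object.
#' @export
predict_psf <- function(config, etl_power_dpt = 0) {
  psf_fwhm(effective_na(config, etl_power_dpt),
           config$input_beam$wavelength_nm,
           config$objective$immersion_index)
}
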