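#' @keywords internal
"_PACKAGE"

# Shared geometry of the modelled excitation path (mm along the unfolded beam,
# origin at the scan-mirror pivot).  The scan lens of the unmodified setup sits
# 56.6 mm after the mirrors, the tube lens 250 mm after the scan lens, and the
# objective back aperture 95 mm after the tube lens.
.path_geom <- list(
  z_scan_lens  = 56.6,
  z_tube_lens  = 306.6,
  z_back_ap    = 401.6,
  etl_position = -200
)

#' Create an optical element (thin lens or free space marker)
#'
#' Elements are ideal thin lenses placed on the unfolded beam path.  Free
#' space between elements is implicit in their axial positions; an explicit
#' `free-space` element can be used to mark a plane of interest.
#'
#' @param kind `"thin-lens"` or `"free-space"`.
#' @param focal_length_mm Focal length in mm (thin lenses only; positive =
#'   converging, `Inf` = flat/no power). Must be nonzero.
#' @param axial_position_mm Position along the unfolded path, mm from the
#'   scan-mirror pivot.
#' @param label Optional name used in printing and error messages.
#' @return An object of class `ntc_element`.
#' @export
optical_element <- function(kind = c("thin-lens", "free-space"),
                            focal_length_mm = Inf,
                            axial_position_mm = 0,
                            label = NULL) {
  kind <- match.arg(kind)
  if (kind == "thin-lens") {
    if (!is.finite(focal_length_mm) && !is.infinite(focal_length_mm))
      stop("focal_length_mm must be a number (possibly Inf)")
    if (identical(focal_length_mm, 0) || focal_length_mm == 0)
      stop("thin lens focal length must be nonzero")
  }
  structure(list(kind = kind,
                 focal_length_mm = focal_length_mm,
                 axial_position_mm = axial_position_mm,
                 label = label %||% kind),
            class = "ntc_element")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Objective model (equivalent thick ideal lens)
#'
#' The objective is represented by a single ideal refracting plane of
#' effective focal length `efl_mm`, placed `principal_standoff_mm` beyond the
#' physical back-aperture ring.  For a long water-immersion 20x/1.0 objective
#' the rear principal plane lies near the front of the housing, tens of mm
#' past the back aperture; collapsing the objective onto the aperture plane
#' would wrongly place the intermediary focus of strongly decollimated trains
#' past the refracting surface.  The limiting aperture of the model is carried
#' at the equivalent-lens plane.
#'
#' @param efl_mm Effective focal length, mm. Default 8.25 (20x objective with
#'   a 165 mm reference tube length).
#' @param max_na Maximum numerical aperture.
#' @param back_aperture_diameter_mm Clear aperture diameter, mm. Defaults to
#'   `2 * max_na * efl_mm`; a warning is emitted if a supplied value differs
#'   from that product by more than 10%.
#' @param nominal_working_distance_mm Nominal working distance, mm.
#' @param immersion_index Refractive index of the immersion medium.
#' @param back_aperture_position_mm Path position of the physical aperture
#'   ring, mm from the mirror pivot.
#' @param principal_standoff_mm Distance from the aperture ring to the
#'   equivalent refracting plane, mm.
#' @return An object of class `ntc_objective`.
#' @export
objective_model <- function(efl_mm = 8.25,
                            max_na = 1.0,
                            back_aperture_diameter_mm = NULL,
                            nominal_working_distance_mm = 1.8,
                            immersion_index = 1.33,
                            back_aperture_position_mm = .path_geom$z_back_ap,
                            principal_standoff_mm = 50) {
  stopifnot(efl_mm > 0, max_na > 0, nominal_working_distance_mm > 0)
  if (immersion_index < 1) stop("immersion_index must be >= 1")
  nominal_ba <- 2 * max_na * efl_mm
  if (is.null(back_aperture_diameter_mm)) {
    back_aperture_diameter_mm <- nominal_ba
  } else if (abs(back_aperture_diameter_mm - nominal_ba) > 0.1 * nominal_ba) {
    warning(sprintf(
      "back aperture diameter %.2f mm deviates >10%% from 2*NA*EFL = %.2f mm",
      back_aperture_diameter_mm, nominal_ba))
  }
  structure(list(efl_mm = efl_mm,
                 max_na = max_na,
                 back_aperture_diameter_mm = back_aperture_diameter_mm,
                 nominal_working_distance_mm = nominal_working_distance_mm,
                 immersion_index = immersion_index,
                 back_aperture_position_mm = back_aperture_position_mm,
                 principal_standoff_mm = principal_standoff_mm),
            class = "ntc_objective")
}

#' Scan mirror model
#'
#' Both galvanometers are collapsed onto a single pivot at the path origin;
#' their separation is unprinted and second order at the angles involved.
#'
#' @param max_optical_half_angle_deg Usable optical half-angle, degrees. `NA`
#'   means "not yet calibrated"; [fov_diameter()] refuses to report a
#'   mirror-limited field until it is set (directly or via [calibrate_optics()]).
#' @param distance_to_first_element_mm Distance to the first lens, mm.
#' @return An object of class `ntc_mirrors`.
#' @export
scan_mirror_model <- function(max_optical_half_angle_deg = NA_real_,
                              distance_to_first_element_mm = .path_geom$z_scan_lens) {
  if (!is.na(max_optical_half_angle_deg) && max_optical_half_angle_deg <= 0)
    stop("max_optical_half_angle_deg must be > 0")
  structure(list(pivot_position_mm = 0,
                 max_optical_half_angle_deg = max_optical_half_angle_deg,
                 distance_to_first_element_mm = distance_to_first_element_mm),
            class = "ntc_mirrors")
}

#' Electrically tunable lens model
#'
#' The ETL sits upstream of the scan mirrors (negative path position).  Its
#' optical power is linear in drive current; its settling dynamics are a
#' linear second-order system fitted to the printed 2-3 ms settling of a
#' 150 um step.
#'
#' @param position_mm Path position (mm; negative = upstream of the pivot).
#' @param diopter_per_mA Optical power gain, dpt/mA. `NA` = calibrate from the
#'   default anchor (50 mA step producing a 600 um focal shift in nTC1).
#' @param max_current_mA Maximum drive current, mA.
#' @param natural_frequency_hz Undamped natural frequency of the settling
#'   model, Hz.
#' @param damping_ratio Damping ratio, in (0, 1].
#' @return An object of class `ntc_etl`.
#' @export
etl_model <- function(position_mm = .path_geom$etl_position,
                      diopter_per_mA = NA_real_,
                      max_current_mA = 300,
                      natural_frequency_hz = 300,
                      damping_ratio = 0.7) {
  stopifnot(max_current_mA > 0, natural_frequency_hz > 0)
  if (damping_ratio <= 0 || damping_ratio > 1)
    stop("damping_ratio must be in (0, 1]")
  structure(list(position_mm = position_mm,
                 diopter_per_mA = diopter_per_mA,
                 max_current_mA = max_current_mA,
                 natural_frequency_hz = natural_frequency_hz,
                 damping_ratio = damping_ratio),
            class = "ntc_etl")
}

#' Gaussian input beam state
#'
#' @param wavelength_nm Vacuum wavelength, nm.
#' @param waist_radius_mm 1/e^2 intensity radius at the waist, mm. `NA` =
#'   calibrate from the default anchor (DL axial two-photon FWHM 3.15 um).
#' @param waist_position_mm Path position of the waist, mm (defaults to the
#'   ETL plane; the beam arrives there collimated).
#' @param medium_index Refractive index at the waist plane.
#' @return An object of class `ntc_beam`.
#' @export
beam_state <- function(wavelength_nm = 927,
                       waist_radius_mm = NA_real_,
                       waist_position_mm = .path_geom$etl_position,
                       medium_index = 1) {
  stopifnot(wavelength_nm > 0)
  if (!is.na(waist_radius_mm) && waist_radius_mm <= 0)
    stop("waist_radius_mm must be > 0")
  structure(list(wavelength_nm = wavelength_nm,
                 waist_radius_mm = waist_radius_mm,
                 waist_position_mm = waist_position_mm,
                 medium_index = medium_index),
            class = "ntc_beam")
}

#' Rayleigh range of a beam state
#'
#' @param beam An [beam_state()] object.
#' @return Rayleigh range in mm.
#' @export
rayleigh_range <- function(beam) {
  lam_mm <- beam$wavelength_nm * 1e-6
  pi * beam$waist_radius_mm^2 * beam$medium_index / lam_mm
}

.preset_elements <- function(preset, lens_distance_mm) {
  g <- .path_geom
  d <- lens_distance_mm
  switch(preset,
    DL = list(
      optical_element("thin-lens", 50,  g$z_scan_lens, "scan lens"),
      optical_element("thin-lens", 200, g$z_tube_lens, "tube lens")),
    nTC1 = list(
      optical_element("thin-lens", 190, g$z_tube_lens - 190, "L1"),
      optical_element("thin-lens", 175, g$z_tube_lens - d,   "L2"),
      optical_element("thin-lens", 200, g$z_tube_lens,       "tube lens")),
    nTC2 = list(
      optical_element("thin-lens", 200, g$z_tube_lens - d, "L3"),
      optical_element("thin-lens", 200, g$z_tube_lens,     "tube lens")),
    stop("unknown preset: ", preset))
}

#' Build an optical configuration for one of the modelled presets
#'
#' `DL` is the unmodified diffraction-limited train (f=50 mm scan lens and
#' f=200 mm tube lens, 250 mm apart, collimating the beam at the objective).
#' `nTC1` replaces the scan lens with L1 (f=190 mm, fixed 190 mm before the
#' tube lens) plus a movable L2 (f=175 mm); `nTC2` uses a single movable L3
#' (f=200 mm).  Moving L2/L3 between 100 mm and ~5 mm from the tube lens sets
#' the intermediary focal point and with it divergence at the objective,
#' trading field of view against excitation N.A.
#'
#' Free model parameters not printed anywhere (input beam waist, usable
#' mirror half-angle, ETL diopter gain, field-curvature sphere radius) default
#' to values calibrated against printed observables of the instrument; see
#' [calibrate_optics()] and [default_calibration()].
#'
#' @param preset `"DL"`, `"nTC1"` or `"nTC2"`.
#' @param lens_distance_mm Distance of the movable lens (L2/L3) from the tube
#'   lens, mm, in `[0, 100]`. Ignored for `DL`.
#' @param wavelength_nm Excitation wavelength, nm.
#' @param objective,mirrors,etl,input_beam Component models; defaults as in
#'   their constructors.
#' @param field_sphere_radius_mm Radius of the (configuration-independent)
#'   spherical focal surface in sample space, mm. `NA` = default calibration.
#' @param calibrated Internal flag; when `TRUE` (default) `NA` free parameters
#'   are filled from [default_calibration()].
#' @return An object of class `ntc_config`.
#' @export
optical_config <- function(preset = c("nTC2", "nTC1", "DL"),
                           lens_distance_mm = 5,
                           wavelength_nm = 927,
                           objective = objective_model(),
                           mirrors = scan_mirror_model(),
                           etl = etl_model(),
                           input_beam = beam_state(wavelength_nm = wavelength_nm),
                           field_sphere_radius_mm = NA_real_,
                           calibrated = TRUE) {
  preset <- match.arg(preset)
  if (preset != "DL" &&
      (lens_distance_mm < 0 || lens_distance_mm > 100))
    stop("lens_distance_mm must be in [0, 100]")
  elements <- .preset_elements(preset, lens_distance_mm)
  pos <- vapply(elements, `[[`, numeric(1), "axial_position_mm")
  if (any(diff(pos) <= 0)) stop("element positions must strictly increase")
  cfg <- structure(list(preset = preset,
                        lens_distance_mm = if (preset == "DL") NA_real_ else lens_distance_mm,
                        elements = elements,
                        objective = objective,
                        mirrors = mirrors,
                        etl = etl,
                        input_beam = input_beam,
                        field_sphere_radius_mm = field_sphere_radius_mm),
                   class = "ntc_config")
  if (calibrated) {
    def <- default_calibration()
    if (is.na(cfg$input_beam$waist_radius_mm))
      cfg$input_beam$waist_radius_mm <- def$waist_radius_mm
    if (is.na(cfg$mirrors$max_optical_half_angle_deg))
      cfg$mirrors$max_optical_half_angle_deg <- def$max_optical_half_angle_deg
    if (is.na(cfg$etl$diopter_per_mA))
      cfg$etl$diopter_per_mA <- def$diopter_per_mA
    if (is.na(cfg$field_sphere_radius_mm))
      cfg$field_sphere_radius_mm <- def$field_sphere_radius_mm
  }
  cfg
}

#' @rdname optical_config
#' @export
optical_preset <- optical_config

#' @export
print.ntc_config <- function(x, ...) {
  cat(sprintf("<ntc_config> preset %s", x$preset))
  if (!is.na(x$lens_distance_mm))
    cat(sprintf(", movable lens %.1f mm from tube lens", x$lens_distance_mm))
  cat("\n  elements:\n")
  for (el in x$elements)
    cat(sprintf("    %-10s f = %6.1f mm at z = %6.1f mm\n",
                el$label, el$focal_length_mm, el$axial_position_mm))
  cat(sprintf("  objective: EFL %.2f mm, NA %.2f, aperture %.1f mm at z = %.1f mm (+%.0f mm standoff)\n",
              x$objective$efl_mm, x$objective$max_na,
              x$objective$back_aperture_diameter_mm,
              x$objective$back_aperture_position_mm,
              x$objective$principal_standoff_mm))
  cat(sprintf("  beam: %.0f nm, w0 = %.3f mm; mirror half-angle %.2f deg; ETL %.4f dpt/mA\n",
              x$input_beam$wavelength_nm, x$input_beam$waist_radius_mm,
              x$mirrors$max_optical_half_angle_deg, x$etl$diopter_per_mA))
  invisible(x)
}
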