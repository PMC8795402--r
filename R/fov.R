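# Field of view and field curvature.

#' Usable field-of-view diameter
#'
#' Reports both the mirror-range-limited diameter (`2 * |dx/dtheta| *
#' theta_max`) and the vignetting-limited diameter (scan angle at which the
#' clipped fraction of the beam-footprint area at the aperture stop reaches
#' `clip_threshold`), and returns their minimum as the usable diameter
#' together with which limit binds.
#'
#' @param config An [optical_config()]; its mirror half-angle must be
#'   calibrated (see [calibrate_optics()]) or supplied here.
#' @param max_optical_half_angle_deg Optional override of the mirror range.
#' @param clip_threshold Vignetted-area fraction defining the usable edge
#'   (default 0.5 = half the beam area clipped).
#' @param etl_power_dpt ETL power, diopters.
#' @return An object of class `ntc_fov`: list with `diameter_mm`,
#'   `mirror_limited_mm`, `vignetting_limited_mm`, `binding`
#'   (`"mirror"`/`"vignetting"`) and `scan_sensitivity_mm_per_rad`.
#' @export
fov_diameter <- function(config, max_optical_half_angle_deg = NULL,
                         clip_threshold = 0.5, etl_power_dpt = 0) {
  th_max <- max_optical_half_angle_deg %||%
    config$mirrors$max_optical_half_angle_deg
  if (is.na(th_max))
    stop("mirror range not calibrated: set max_optical_half_angle_deg ",
         "(directly or via calibrate_optics with a field-of-view observable)")
  s <- abs(.scan_sensitivity(config, etl_power_dpt))
  mirror_mm <- 2 * s * .deg2rad(th_max)
  # vignetting-limited angle: clipped area fraction reaches clip_threshold
  f0 <- .vignetting_fraction(config, 0, etl_power_dpt)
  vig_mm <- if (f0 >= clip_threshold) {
    0
  } else {
    obj <- config$objective
    z_stop <- obj$back_aperture_position_mm + obj$principal_standoff_mm
    a <- obj$back_aperture_diameter_mm / 2
    w <- propagate_gaussian(config$input_beam, config, z_stop,
                            etl_power_dpt)$radius_mm
    hp <- abs(.chief_height_at_stop(config, etl_power_dpt))
    th_hi <- (a + w) / hp * 1.01
    th50 <- stats::uniroot(function(th)
      .vignetting_fraction(config, th, etl_power_dpt) - clip_threshold,
      c(0, th_hi), tol = 1e-12)$root
    2 * s * th50
  }
  binding <- if (mirror_mm <= vig_mm) "mirror" else "vignetting"
  structure(list(diameter_mm = min(mirror_mm, vig_mm),
                 mirror_limited_mm = mirror_mm,
                 vignetting_limited_mm = vig_mm,
                 binding = binding,
                 clip_threshold = clip_threshold,
                 scan_sensitivity_mm_per_rad = s), class = "ntc_fov")
}

#' @export
print.ntc_fov <- function(x, ...) {
  cat(sprintf("<ntc_fov> usable diameter %.3f mm (%s-limited; mirror %.3f mm, vignetting %.3f mm)\n",
              x$diameter_mm, x$binding, x$mirror_limited_mm,
              x$vignetting_limited_mm))
  invisible(x)
}

#' Field-curvature sagitta (centre minus edge focus depth)
#'
#' Evaluates [focus_solution()] on axis and at the field edge and returns
#' `z_centre - z_edge` in um.  With the sign convention that z increases away
#' from the objective and the field edges bend towards it (the "upwards bend"
#' of large-field scans), the sagitta is non-negative.
#'
#' @param config An [optical_config()].
#' @param fov_mm Field diameter over which to evaluate the edge, mm.
#'   Defaults to the usable [fov_diameter()].
#' @param etl_power_dpt ETL power, diopters.
#' @return Sagitta in um.
#' @export
field_curvature_sagitta <- function(config, fov_mm = NULL,
                                    etl_power_dpt = 0) {
  if (is.null(fov_mm)) fov_mm <- fov_diameter(config,
                                              etl_power_dpt = etl_power_dpt)$diameter_mm
  r <- fov_mm / 2
  s <- .scan_sensitivity(config, etl_power_dpt)
  th_edge <- .rad2deg(r / abs(s))
  z_c <- focus_solution(config, 0, 0, etl_power_dpt)$focus_point_um["z"]
  # evaluate edge without tripping the mirror-range precondition: the edge of
  # a supplied fov_mm may exceed the calibrated scan range
  cfg <- config
  cfg$mirrors$max_optical_half_angle_deg <- NA_real_
  z_e <- focus_solution(cfg, th_edge, 0, etl_power_dpt)$focus_point_um["z"]
  unname(z_c - z_e)
}
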