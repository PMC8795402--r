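# Focus solutions, IFP location, effective N.A., vignetting.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# Lateral scan sensitivity: mm of focal-plane displacement per rad of optical
# scan angle at the mirrors (signed).  Immersion cancels out of the lateral
# mapping: x = y_obj + L_air * u_obj.
.scan_sensitivity <- function(config, etl_power_dpt = 0) {
  L_air <- .geometric_focus(config, etl_power_dpt) /
    config$objective$immersion_index
  th <- 1e-4
  ch <- .trace_ray(config, 0, th, start_z = 0, etl_power_dpt = etl_power_dpt)
  (ch$y + L_air * ch$u) / th
}

# Chief-ray height at the aperture-stop plane per rad of scan angle.
.chief_height_at_stop <- function(config, etl_power_dpt = 0) {
  z_stop <- config$objective$back_aperture_position_mm +
    config$objective$principal_standoff_mm
  th <- 1e-4
  .ray_height_at(config, 0, th, start_z = 0, plane_z = z_stop,
                 etl_power_dpt = etl_power_dpt) / th
}

# Area of intersection of two discs (radii r1, r2, centre distance d).
.disc_overlap_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

# Fraction of the 1/e^2 beam disc area clipped by the aperture stop when the
# beam centroid is offset h from the stop centre.
.vignetting_fraction <- function(config, theta_rad, etl_power_dpt = 0) {
  obj <- config$objective
  z_stop <- obj$back_aperture_position_mm + obj$principal_standoff_mm
  a <- obj$back_aperture_diameter_mm / 2
  w <- propagate_gaussian(config$input_beam, config, z_stop,
                          etl_power_dpt)$radius_mm
  h <- abs(.chief_height_at_stop(config, etl_power_dpt) * theta_rad)
  1 - .disc_overlap_area(a, w, h) / (pi * w^2)
}

# Sagitta (mm, >= 0) of the spherical focal surface at field radius r_mm.
.field_sagitta_mm <- function(config, r_mm) {
  R <- config$field_sphere_radius_mm
  if (is.na(R)) stop("field_sphere_radius_mm not set")
  if (abs(r_mm) >= R) stop("field radius exceeds the focal sphere radius")
  R - sqrt(R^2 - r_mm^2)
}

#' Locate the intermediary focal point (IFP)
#'
#' Traces the axial marginal ray through the train (without the objective)
#' and finds where it crosses the axis between the scan mirrors and the
#' objective.  In the DL train the crossing lies between the scan lens and
#' the tube lens and the output is collimated; in nTC1 the movable L2 pulls
#' it to just upstream of the tube lens; in nTC2 the crossing (after
#' refraction by the tube lens) lies downstream of the tube lens.
#'
#' @param config An [optical_config()].
#' @param etl_power_dpt ETL power, diopters.
#' @return A list with `position_mm` (path position of the IFP),
#'   `rel_tube_lens_mm` (signed; negative = upstream of the tube lens) and
#'   `collimated_after_tube_lens` (logical).  If the beam never crosses the
#'   axis before the objective, `position_mm` is `NA` and the state is
#'   reported as collimated.
#' @export
find_ifp <- function(config, etl_power_dpt = 0) {
  tab <- .path_table(config, etl_power_dpt)
  tab <- tab[tab$label != "objective", , drop = FALSE]
  z_obj <- config$objective$back_aperture_position_mm +
    config$objective$principal_standoff_mm
  z_tl <- max(tab$z)
  y <- config$input_beam$waist_radius_mm; u <- 0; z <- config$etl$position_mm
  crossings <- numeric(0)
  segs <- rbind(tab[, c("z", "f")], data.frame(z = z_obj, f = Inf))
  for (i in seq_len(nrow(segs))) {
    zi <- segs$z[i]
    if (zi > z && u != 0) {
      zc <- z - y / u
      if (zc > z + 1e-9 && zc < zi - 1e-9) crossings <- c(crossings, zc)
    }
    y <- y + (zi - z) * u; z <- zi
    if (is.finite(segs$f[i])) u <- u - y / segs$f[i]
  }
  # state after the tube lens (last train element)
  after_tl <- .trace_ray(config, config$input_beam$waist_radius_mm, 0,
                         etl_power_dpt = etl_power_dpt, stop_z = z_tl + 1e-6)
  collim <- abs(after_tl$u) * z_obj < 1e-6 * abs(after_tl$y)
  ifp <- if (length(crossings)) crossings[length(crossings)] else NA_real_
  list(position_mm = ifp,
       rel_tube_lens_mm = if (is.na(ifp)) NA_real_ else ifp - z_tl,
       collimated_after_tube_lens = collim)
}

#' Effective excitation numerical aperture
#'
#' N.A. of the focused Gaussian cone in the immersion medium,
#' `n * sin(theta) ~ lambda0 / (pi * w_f)` with `w_f` the focused 1/e^2
#' waist from the complex-beam-parameter trace.  Clamped at the objective's
#' maximum N.A.; a diverging beam at the aperture underfills it and lowers
#' the value.
#'
#' @param config An [optical_config()].
#' @param etl_power_dpt ETL power, diopters.
#' @return Dimensionless N.A.
#' @export
effective_na <- function(config, etl_power_dpt = 0) {
  gf <- .gaussian_focus(config, etl_power_dpt)
  min(gf$na, config$objective$max_na)
}

#' Focus solution for a mirror/ETL state
#'
#' Chief-ray trace gives the lateral focus position; the marginal-ray
#' crossing gives the axial focus; the spherical focal surface bends the
#' field edges towards the objective; the beam footprint against the
#' aperture stop gives the vignetting fraction.
#'
#' @param config An [optical_config()].
#' @param theta_x_deg,theta_y_deg Optical scan angles, degrees.
#' @param etl_power_dpt ETL power, diopters (alternatively give
#'   `etl_current_mA`).
#' @param etl_current_mA ETL drive current; converted with the calibrated
#'   diopter gain.
#' @return An object of class `ntc_focus`: list with `focus_point_um`
#'   (x, y, z; z measured from the nominal focal plane, positive away from
#'   the objective), `effective_na`, `beam_radius_at_aperture_mm`,
#'   `divergence_half_angle_rad`, `ifp`, `vignetting_fraction` and
#'   `fully_vignetted` flag.
#' @export
focus_solution <- function(config, theta_x_deg = 0, theta_y_deg = 0,
                           etl_power_dpt = 0, etl_current_mA = NULL) {
  if (!is.null(etl_current_mA)) {
    if (abs(etl_current_mA) > config$etl$max_current_mA)
      stop(sprintf("ETL current %.1f mA exceeds max %.1f mA",
                   etl_current_mA, config$etl$max_current_mA))
    etl_power_dpt <- config$etl$diopter_per_mA * etl_current_mA
  }
  th_max <- config$mirrors$max_optical_half_angle_deg
  if (!is.na(th_max) &&
      max(abs(theta_x_deg), abs(theta_y_deg)) > th_max + 1e-9)
    stop(sprintf("scan angle exceeds calibrated half-angle %.3f deg", th_max))
  n <- config$objective$immersion_index
  tx <- .deg2rad(theta_x_deg); ty <- .deg2rad(theta_y_deg)
  s <- .scan_sensitivity(config, etl_power_dpt)
  x_mm <- s * tx; y_mm <- s * ty
  r_mm <- sqrt(x_mm^2 + y_mm^2)
  L_w <- .geometric_focus(config, etl_power_dpt)
  z0_w <- n * config$objective$efl_mm
  z_um <- (L_w - z0_w) * 1000 - 1000 * .field_sagitta_mm(config, r_mm)
  th_r <- sqrt(tx^2 + ty^2)
  vig <- .vignetting_fraction(config, th_r, etl_power_dpt)
  z_stop <- config$objective$back_aperture_position_mm +
    config$objective$principal_standoff_mm
  pg <- propagate_gaussian(config$input_beam, config, z_stop, etl_power_dpt)
  # slope of the 1/e^2 edge ray at the stop (geometric part of divergence)
  edge <- .trace_ray(config, config$input_beam$waist_radius_mm, 0,
                     etl_power_dpt = etl_power_dpt, stop_z = z_stop - 1e-6)
  structure(list(
    focus_point_um = c(x = x_mm * 1000, y = y_mm * 1000, z = z_um),
    effective_na = effective_na(config, etl_power_dpt),
    beam_radius_at_aperture_mm = pg$radius_mm,
    divergence_half_angle_rad = edge$u,
    ifp = find_ifp(config, etl_power_dpt),
    vignetting_fraction = vig,
    fully_vignetted = vig >= 1 - 1e-12,
    scan_sensitivity_mm_per_rad = s), class = "ntc_focus")
}

#' @export
print.ntc_focus <- function(x, ...) {
  p <- x$focus_point_um
  cat(sprintf("<ntc_focus> (x, y, z) = (%.1f, %.1f, %.1f) um, N.A. %.3f, vignetting %.1f%%%s\n",
              p[1], p[2], p[3], x$effective_na, 100 * x$vignetting_fraction,
              if (x$fully_vignetted) " [fully vignetted]" else ""))
  invisible(x)
}

#' Axial focus shift produced by an ETL drive current
#'
#' Converts current to diopters with the calibrated gain and reports the
#' focal-plane shift relative to zero current, positive towards the
#' objective (an "elevated" plane).
#'
#' @param config An [optical_config()].
#' @param current_mA Drive current, mA; must not exceed the ETL maximum.
#' @return Focus shift in um.
#' @export
etl_current_to_focus_shift <- function(config, current_mA) {
  if (abs(current_mA) > config$etl$max_current_mA)
    stop(sprintf("current %.1f mA exceeds ETL maximum %.1f mA",
                 current_mA, config$etl$max_current_mA))
  phi <- config$etl$diopter_per_mA * current_mA
  n <- config$objective$immersion_index
  z0 <- .geometric_focus(config, 0)
  z1 <- .geometric_focus(config, phi)
  (z0 - z1) * 1000
}
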