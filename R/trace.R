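# Paraxial ray-matrix core.
#
# Rays are (y, u) column vectors: height mm, slope rad.  All refractive
# elements are ideal thin lenses; free space is implicit between element
# positions.  The sample space beyond the objective's equivalent lens plane
# is immersed (index n); crossing the flat air/water interface multiplies
# image distances by n and divides slopes by n, leaving lateral positions of
# focus unchanged.

.lens_matrix <- function(f) matrix(c(1, 0, -1 / f, 1), 2, 2, byrow = TRUE)
.space_matrix <- function(d) matrix(c(1, d, 0, 1), 2, 2, byrow = TRUE)

# Full refracting-surface table for a config at a given ETL power:
# data.frame(z, f, label), ordered, ETL first, objective last.
.path_table <- function(config, etl_power_dpt = 0) {
  lenses <- Filter(function(e) e$kind == "thin-lens", config$elements)
  z <- vapply(lenses, `[[`, numeric(1), "axial_position_mm")
  f <- vapply(lenses, `[[`, numeric(1), "focal_length_mm")
  lab <- vapply(lenses, `[[`, character(1), "label")
  etl_f <- if (abs(etl_power_dpt) > 0) 1000 / etl_power_dpt else Inf
  z_obj <- config$objective$back_aperture_position_mm +
    config$objective$principal_standoff_mm
  out <- data.frame(
    z = c(config$etl$position_mm, z, z_obj),
    f = c(etl_f, f, config$objective$efl_mm),
    label = c("ETL", lab, "objective"),
    stringsAsFactors = FALSE)
  out[order(out$z), , drop = FALSE]
}

#' Composite ray transfer matrix between two path planes
#'
#' Composes the ABCD matrices of all thin lenses with positions in
#' `(from_position_mm, to_position_mm]` together with the free-space
#' translations between them.  Both endpoints must lie on the modelled path
#' (from the ETL plane to the objective's equivalent lens plane).
#'
#' @param config An [optical_config()].
#' @param from_position_mm,to_position_mm Path positions in mm,
#'   `from_position_mm < to_position_mm`.
#' @param etl_power_dpt ETL optical power in diopters.
#' @return A 2x2 ABCD matrix.
#' @export
transfer_matrix <- function(config, from_position_mm, to_position_mm,
                            etl_power_dpt = 0) {
  if (from_position_mm >= to_position_mm)
    stop("from_position_mm must be < to_position_mm")
  tab <- .path_table(config, etl_power_dpt)
  lo <- min(tab$z); hi <- max(tab$z)
  if (from_position_mm < lo - 1e-9 || to_position_mm > hi + 1e-9)
    stop(sprintf("positions must lie within the modelled path [%.1f, %.1f] mm", lo, hi))
  if (any(tab$f == 0)) stop("zero-focal-length element on path")
  m <- diag(2)
  z <- from_position_mm
  sel <- tab$z > from_position_mm + 1e-12 & tab$z <= to_position_mm + 1e-12
  for (i in which(sel)) {
    m <- .lens_matrix(tab$f[i]) %*% .space_matrix(tab$z[i] - z) %*% m
    z <- tab$z[i]
  }
  if (to_position_mm > z) m <- .space_matrix(to_position_mm - z) %*% m
  m
}

# Trace a geometric ray (y0, u0) from start_z through all refracting surfaces
# at z > start_z (up to and including the objective).  Returns y, u after the
# last surface and the surface positions passed.
.trace_ray <- function(config, y0, u0, start_z = NULL, etl_power_dpt = 0,
                       stop_z = Inf) {
  tab <- .path_table(config, etl_power_dpt)
  z <- start_z %||% (tab$z[1] - 1e-6)
  y <- y0; u <- u0
  for (i in seq_len(nrow(tab))) {
    if (tab$z[i] <= z + 1e-12 || tab$z[i] > stop_z) next
    y <- y + (tab$z[i] - z) * u
    z <- tab$z[i]
    if (is.finite(tab$f[i])) u <- u - y / tab$f[i]
  }
  list(y = y, u = u, z = z)
}

# Height of a ray at an intermediate plane (before refraction at that plane).
.ray_height_at <- function(config, y0, u0, start_z, plane_z, etl_power_dpt = 0) {
  r <- .trace_ray(config, y0, u0, start_z, etl_power_dpt,
                  stop_z = plane_z - 1e-9)
  r$y + (plane_z - r$z) * r$u
}

#' Propagate a Gaussian beam to a plane on the path
#'
#' Transports the complex beam parameter of `beam` through the configuration
#' with [transfer_matrix()] and reports the 1/e^2 intensity radius and
#' wavefront radius of curvature at the requested plane (before refraction by
#' any element sitting exactly there).
#'
#' @param beam A [beam_state()]; its waist position anchors the propagation.
#' @param config An [optical_config()].
#' @param to_position_mm Target plane, mm along the path.
#' @param etl_power_dpt ETL optical power, diopters.
#' @return A list with `radius_mm` (1/e^2 intensity radius),
#'   `curvature_radius_mm` (signed wavefront radius, `Inf` at a waist),
#'   `q` (complex beam parameter) and the input `beam`.
#' @export
propagate_gaussian <- function(beam, config, to_position_mm,
                               etl_power_dpt = 0) {
  if (is.na(beam$waist_radius_mm) || beam$waist_radius_mm <= 0)
    stop("non-physical beam: waist_radius_mm must be > 0")
  lam <- beam$wavelength_nm * 1e-6 / beam$medium_index
  q0 <- complex(real = 0, imaginary = pi * beam$waist_radius_mm^2 / lam)
  m <- transfer_matrix(config, beam$waist_position_mm, to_position_mm,
                       etl_power_dpt)
  # exclude refraction by an element exactly at the target plane
  tab <- .path_table(config, etl_power_dpt)
  at <- which(abs(tab$z - to_position_mm) < 1e-9)
  if (length(at) == 1 && is.finite(tab$f[at]))
    m <- .lens_matrix(-tab$f[at]) %*% m  # undo that lens
  q <- (m[1, 1] * q0 + m[1, 2]) / (m[2, 1] * q0 + m[2, 2])
  w <- sqrt(lam / (pi * Im(-1 / q)))
  rcurv <- 1 / Re(1 / q)
  list(radius_mm = w,
       curvature_radius_mm = if (is.finite(rcurv)) rcurv else Inf,
       q = q, beam = beam)
}

# Complex q just after the objective, converted into the immersion medium,
# plus derived focus quantities.  Distances from the objective's equivalent
# lens plane, in sample (water) space.
.gaussian_focus <- function(config, etl_power_dpt = 0) {
  beam <- config$input_beam
  if (is.na(beam$waist_radius_mm)) stop("input beam waist not set")
  lam0 <- beam$wavelength_nm * 1e-6
  n <- config$objective$immersion_index
  tab <- .path_table(config, etl_power_dpt)
  q <- complex(real = 0, imaginary = pi * beam$waist_radius_mm^2 / lam0)
  z <- beam$waist_position_mm - 1e-6
  for (i in seq_len(nrow(tab))) {
    if (tab$z[i] <= z) next
    q <- q + (tab$z[i] - z); z <- tab$z[i]
    if (is.finite(tab$f[i])) q <- q / (1 - q / tab$f[i])
  }
  qn <- q * n                      # flat interface into immersion
  z_waist <- -Re(qn)               # waist distance beyond objective plane, water
  z_rayleigh <- Im(qn + z_waist)
  waist_mm <- sqrt(z_rayleigh * lam0 / (pi * n))
  list(z_waist_mm = z_waist, z_rayleigh_mm = z_rayleigh,
       waist_radius_mm = waist_mm,
       na = lam0 / (pi * waist_mm))
}

# Geometric focus: crossing distance (water space, mm beyond the objective
# equivalent plane) of an input-parallel marginal ray.
.geometric_focus <- function(config, etl_power_dpt = 0) {
  r <- .trace_ray(config, 1, 0, etl_power_dpt = etl_power_dpt)
  n <- config$objective$immersion_index
  if (abs(r$u) < 1e-15) return(Inf)
  n * (-r$y / r$u)
}

#' Lagrange invariant of a chief/marginal ray pair
#'
#' Computes `n * (y_chief * u_marginal - y_marginal * u_chief)` at every
#' element plane of the path (air space).  For an ideal paraxial train the
#' value is identical at all planes.
#'
#' @param config An [optical_config()].
#' @param theta_rad Chief-ray angle at the mirror pivot, rad.
#' @param marginal_height_mm Marginal-ray height at the pivot, mm.
#' @param etl_power_dpt ETL power, diopters.
#' @return Numeric vector of the invariant evaluated after each surface.
#' @export
lagrange_invariant <- function(config, theta_rad = 0.01,
                               marginal_height_mm = 1,
                               etl_power_dpt = 0) {
  tab <- .path_table(config, etl_power_dpt)
  ch <- c(0, theta_rad); mg <- c(marginal_height_mm, 0)
  # chief starts at the pivot (z = 0), marginal at the ETL plane
  vals <- numeric(0)
  zc <- 0; zm <- tab$z[1]
  for (i in seq_len(nrow(tab))) {
    zi <- tab$z[i]
    if (zi > zm) { mg[1] <- mg[1] + (zi - zm) * mg[2]; zm <- zi }
    if (zi > zc) { ch[1] <- ch[1] + (zi - zc) * ch[2]; zc <- zi }
    if (zi >= 0 && is.finite(tab$f[i])) {
      ch[2] <- ch[2] - ch[1] / tab$f[i]
      mg[2] <- mg[2] - mg[1] / tab$f[i]
      vals <- c(vals, ch[1] * mg[2] - mg[1] * ch[2])
    } else if (is.finite(tab$f[i])) {
      mg[2] <- mg[2] - mg[1] / tab$f[i]
    }
  }
  vals
}
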