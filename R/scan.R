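# Scan patterns: regions, z-profiles, timing.
#
# A scan pattern is an ordered list of scan regions cycled once per frame.
# The fast (x) mirror sweeps each line; the slow (y) mirror steps per line;
# the ETL command is piecewise constant per line and realizes the region's
# z-profile.  The stated ms-per-line includes the turnaround, so the printed
# frame rates equal 1 / (n_lines * line_period) exactly.

#' Axial (z) profile of a scan region
#'
#' @param kind One of `"flat"`, `"staircase"`, `"tilted"`, `"halfpipe"`,
#'   `"multiplane"`.
#' @param offset_um Constant offset for `flat`, um.
#' @param jump_line 1-based line index at which a `staircase` steps.
#' @param dz_um Staircase step size, um.
#' @param angle_deg Tilt of a `tilted` plane relative to the focal plane,
#'   degrees (|angle| < 90); the z-ramp follows the slow-axis position so
#'   that the y image dimension represents matched y and z movement.
#' @param peak_um Peak axial displacement of a `halfpipe` at the scan centre,
#'   um.  The ETL drive follows `sqrt(cos())` of the slow-axis phase,
#'   clipped at zero.
#' @param plane_offsets_um Numeric vector of per-plane offsets for
#'   `multiplane`, um.
#' @return An object of class `ntc_zprofile`.
#' @export
z_profile <- function(kind = c("flat", "staircase", "tilted", "halfpipe",
                               "multiplane"),
                      offset_um = 0, jump_line = NULL, dz_um = NULL,
                      angle_deg = NULL, peak_um = NULL,
                      plane_offsets_um = NULL) {
  kind <- match.arg(kind)
  p <- switch(kind,
    flat = list(offset_um = offset_um),
    staircase = {
      if (is.null(jump_line) || is.null(dz_um))
        stop("staircase needs jump_line and dz_um")
      list(jump_line = jump_line, dz_um = dz_um, offset_um = offset_um)
    },
    tilted = {
      if (is.null(angle_deg)) stop("tilted needs angle_deg")
      if (abs(angle_deg) >= 90) stop("|angle_deg| must be < 90")
      list(angle_deg = angle_deg, offset_um = offset_um)
    },
    halfpipe = {
      if (is.null(peak_um)) stop("halfpipe needs peak_um")
      list(peak_um = peak_um, offset_um = offset_um)
    },
    multiplane = {
      if (is.null(plane_offsets_um) || !length(plane_offsets_um))
        stop("multiplane needs plane_offsets_um")
      list(plane_offsets_um = plane_offsets_um)
    })
  structure(c(list(kind = kind), p), class = "ntc_zprofile")
}

#' Per-line axial displacement of a z-profile
#'
#' @param profile An [z_profile()].
#' @param n_lines Number of lines in the region.
#' @param y_extent_um Slow-axis extent of the region, um (used by `tilted`).
#' @return Numeric vector of length `n_lines`, um.
#' @export
profile_z_um <- function(profile, n_lines, y_extent_um = 0) {
  l <- seq_len(n_lines)
  switch(profile$kind,
    flat = rep(profile$offset_um, n_lines),
    staircase = {
      if (profile$jump_line < 1 || profile$jump_line > n_lines)
        stop("jump_line outside the region's line count")
      profile$offset_um + ifelse(l >= profile$jump_line, profile$dz_um, 0)
    },
    tilted = {
      y <- if (n_lines > 1) (l - 1) / (n_lines - 1) - 0.5 else 0
      profile$offset_um + tan(profile$angle_deg * pi / 180) * y * y_extent_um
    },
    halfpipe = {
      x <- if (n_lines > 1) (l - 1) / (n_lines - 1) else 0.5
      profile$offset_um +
        profile$peak_um * sqrt(pmax(cos(pi * (x - 0.5)), 0))
    },
    multiplane = {
      k <- length(profile$plane_offsets_um)
      if (n_lines %% k != 0)
        stop("multiplane needs n_lines divisible by the number of planes")
      rep(profile$plane_offsets_um, each = n_lines / k)
    })
}

#' Define a scan region
#'
#' @param n_lines Number of scan lines (slow-axis samples), >= 1.
#' @param pixels_per_line Pixels along the fast axis, >= 1.
#' @param line_period_ms Duration of one line, ms (includes the turnaround).
#' @param x0_um,y0_um Lateral centre of the region in field coordinates, um.
#' @param width_um,height_um Lateral extent, um.
#' @param zprofile An [z_profile()]; default flat at 0.
#' @return An object of class `ntc_region`.
#' @export
scan_region <- function(n_lines, pixels_per_line, line_period_ms = 1,
                        x0_um = 0, y0_um = 0,
                        width_um = 100, height_um = 100,
                        zprofile = z_profile("flat")) {
  stopifnot(n_lines >= 1, pixels_per_line >= 1)
  if (line_period_ms <= 0) stop("line_period_ms must be > 0")
  structure(list(n_lines = as.integer(n_lines),
                 pixels_per_line = as.integer(pixels_per_line),
                 line_period_ms = line_period_ms,
                 x0_um = x0_um, y0_um = y0_um,
                 width_um = width_um, height_um = height_um,
                 zprofile = zprofile), class = "ntc_region")
}

.region_extent_check <- function(region, fov_um) {
  if (is.null(fov_um)) return(invisible(TRUE))
  half <- fov_um / 2
  xr <- abs(region$x0_um) + region$width_um / 2
  yr <- abs(region$y0_um) + region$height_um / 2
  if (xr > half || yr > half)
    stop(sprintf(paste0("region extends to %.0f um from the field centre but ",
                        "the configured field of view allows %.0f um"),
                 max(xr, yr), half))
  invisible(TRUE)
}

#' Assemble a scan pattern from regions
#'
#' @param regions List of [scan_region()]s, cycled in order once per frame.
#' @param transition_lines Blanked lines consumed by each jump between
#'   consecutive regions (including the wrap-around back to the first);
#'   default 2, after the two 1 ms lines the real system needs for a ~1 mm
#'   jump.  Single-region patterns have no transitions.
#' @param repeat_count Frames per acquisition (bookkeeping only).
#' @param fov_um Optional usable field diameter, um; regions outside it are
#'   rejected.
#' @return An object of class `ntc_pattern`.
#' @export
scan_pattern <- function(regions, transition_lines = 2, repeat_count = 1,
                         fov_um = NULL) {
  if (!length(regions)) stop("need at least one region")
  if (transition_lines < 0) stop("transition_lines must be >= 0")
  lapply(regions, .region_extent_check, fov_um = fov_um)
  structure(list(regions = regions,
                 transition_lines = as.integer(transition_lines),
                 repeat_count = repeat_count,
                 fov_um = fov_um), class = "ntc_pattern")
}

#' Build a single-region raster pattern
#'
#' @inheritParams scan_region
#' @param extent_um Square lateral extent, um.
#' @param fov_um Optional usable field diameter, um.
#' @return An `ntc_pattern` with one flat region and no transitions.
#' @export
build_raster <- function(n_lines, pixels_per_line, line_period_ms = 1,
                         extent_um = 100, fov_um = NULL,
                         zprofile = z_profile("flat")) {
  region <- scan_region(n_lines, pixels_per_line, line_period_ms,
                        width_um = extent_um, height_um = extent_um,
                        zprofile = zprofile)
  scan_pattern(list(region), transition_lines = 0L, fov_um = fov_um)
}

#' Build a random-access pattern over multiple regions
#'
#' Regions are interleaved within each frame; each inter-region jump
#' consumes `transition_lines` blanked lines.
#'
#' @param regions List of >= 2 [scan_region()]s (a single region degenerates
#'   to the raster case with no transitions).
#' @param transition_lines Blanked lines per jump.
#' @param fov_um Optional usable field diameter, um.
#' @return An `ntc_pattern`.
#' @export
build_random_access <- function(regions, transition_lines = 2,
                                fov_um = NULL) {
  if (length(regions) < 2)
    return(scan_pattern(regions, transition_lines = 0L, fov_um = fov_um))
  scan_pattern(regions, transition_lines = transition_lines, fov_um = fov_um)
}

#' Per-line ETL commands realizing a region's z-profile
#'
#' @param region An [scan_region()].
#' @param profile An [z_profile()]; defaults to the region's own.
#' @param etl_calibration Either `NULL` (commands reported in um), a scalar
#'   (um of focal shift per diopter) or an [optical_config()] from which that
#'   scale and the available z-range are derived.
#' @return data.frame with `line`, `z_um` and (when a calibration is given)
#'   `etl_dpt`.
#' @export
apply_z_profile <- function(region, profile = region$zprofile,
                            etl_calibration = NULL) {
  z <- profile_z_um(profile, region$n_lines, region$height_um)
  out <- data.frame(line = seq_len(region$n_lines), z_um = z)
  if (!is.null(etl_calibration)) {
    if (inherits(etl_calibration, "ntc_config")) {
      cfg <- etl_calibration
      um_per_dpt <- abs(etl_current_to_focus_shift(cfg, 1) /
                          cfg$etl$diopter_per_mA)
      zmax <- abs(etl_current_to_focus_shift(cfg, cfg$etl$max_current_mA))
      over <- max(abs(z)) - zmax
      if (over > 0)
        stop(sprintf("z-profile exceeds the calibrated ETL range by %.1f um",
                     over))
      out$etl_dpt <- z / um_per_dpt
    } else {
      out$etl_dpt <- z / etl_calibration
    }
  }
  out
}

#' Exact timing report of a scan pattern
#'
#' Line periods are converted to integer microseconds and summed exactly;
#' rates are reported both with and without the blanked transition lines
#' (whether the printed rates of multi-region scans include transitions is
#' not stated by the protocol, so both are available).
#'
#' @param pattern An `ntc_pattern`.
#' @return An object of class `ntc_timing`: list with `frame_rate_hz`,
#'   `frame_rate_active_only_hz`, `per_plane_rate_hz` (for a multiplane
#'   single region: the volume rate), `total_lines`, `transition_lines_total`,
#'   `transition_duration_ms`, `cycle_duration_ms`.
#' @export
timing_report <- function(pattern) {
  lines <- vapply(pattern$regions, `[[`, integer(1), "n_lines")
  per_us <- vapply(pattern$regions, function(r)
    round(r$line_period_ms * 1000), numeric(1))
  n_trans <- if (length(pattern$regions) > 1)
    length(pattern$regions) * pattern$transition_lines else 0L
  trans_us <- if (length(pattern$regions) > 1)
    pattern$transition_lines * per_us[1] * length(pattern$regions) else 0
  active_us <- sum(lines * per_us)
  total_us <- active_us + trans_us
  k <- length(pattern$regions)
  planes <- if (k == 1 && pattern$regions[[1]]$zprofile$kind == "multiplane")
    length(pattern$regions[[1]]$zprofile$plane_offsets_um) else k
  structure(list(frame_rate_hz = 1e6 / total_us,
                 frame_rate_active_only_hz = 1e6 / active_us,
                 per_plane_rate_hz = 1e6 / total_us,
                 n_planes = planes,
                 total_lines = sum(lines) + n_trans,
                 transition_lines_total = n_trans,
                 transition_duration_ms = trans_us / 1000,
                 cycle_duration_ms = total_us / 1000), class = "ntc_timing")
}

#' @export
print.ntc_timing <- function(x, ...) {
  cat(sprintf("<ntc_timing> %.4g Hz (%.4g Hz active-only), cycle %.3f ms, %d lines (%d transition)\n",
              x$frame_rate_hz, x$frame_rate_active_only_hz,
              x$cycle_duration_ms, x$total_lines, x$transition_lines_total))
  invisible(x)
}
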