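# Rendering simulated acquisitions from phantoms.
#
# The excitation volume is the squared-intensity 3D Gaussian with FWHMs from
# the PSF model, oriented along the local chief ray (edge tilt).  A sphere of
# diameter D is approximated by a Gaussian of matched variance (sigma =
# D/sqrt(20) per axis), so the emitter-PSF overlap integral is a product of
# 1-D Gaussian convolutions; sub-PSF emitters converge to the bare PSF and
# PSF-sized emitters stay bright while smaller ones dim, reproducing the
# optical-merging behaviour of enlarged excitation volumes.

# Radially sampled vignetting interpolator (r in mm).
.vignetting_interp <- function(config, r_max_mm, n = 33) {
  s <- abs(.scan_sensitivity(config))
  r <- seq(0, max(r_max_mm, 1e-6), length.out = n)
  v <- vapply(r / s, function(th) .vignetting_fraction(config, th), numeric(1))
  stats::approxfun(r, v, rule = 2)
}

# Chief-ray tilt (rad per mm of field radius) in sample space.
.tilt_per_mm <- function(config) {
  th <- 1e-4
  ch <- .trace_ray(config, 0, th, start_z = 0)
  s <- .scan_sensitivity(config)
  n <- config$objective$immersion_index
  (ch$u / n) / s  # rad of chief tilt per mm lateral
}

.pattern_hash <- function(pattern) .hash_obj(unclass(pattern))

#' Render a scan of a phantom
#'
#' Computes, for every pixel of every region, the focus coordinates implied
#' by the optical configuration (field curvature included), the region's
#' z-profile and the stage offset, and accumulates each emitter's
#' Gaussian-overlap contribution scaled by the squared transmitted power
#' under vignetting.
#'
#' @param config An [optical_config()].
#' @param pattern An `ntc_pattern` (lateral units um).
#' @param phantom An [make_phantom()] phantom.
#' @param stage_z_um Numeric vector of stage offsets; each entry renders one
#'   frame (a z-stack when stepped).
#' @param refocus When `TRUE` (default) the sample is parked at the
#'   configuration's own on-axis focal plane (as a user would refocus the
#'   objective onto the preparation), so `stage_z_um = 0` images the phantom
#'   plane `z = 0`; `FALSE` keeps absolute focal depths.
#' @param psf Optional `ntc_psf` override; default [predict_psf()].
#' @param noise_sd Additive Gaussian noise s.d.
#' @param seed RNG seed used for the noise (recorded in provenance).
#' @param brightness_scale Optional matrix `[frame, emitter]` of
#'   multiplicative brightness factors (used by [render_timeseries()]).
#' @return An object of class `ntc_acquired`: list with `pixels`
#'   `[frame, line, pixel]`, axes `x_um`, `y_um`, `stage_z_um`,
#'   `pixel_size_um`, `focus_z_um` (per line x pixel at stage 0) and
#'   `provenance`.
#' @export
render_scan <- function(config, pattern, phantom, stage_z_um = 0,
                        psf = NULL, noise_sd = 0, seed = NULL,
                        brightness_scale = NULL, refocus = TRUE) {
  if (length(pattern$regions) != 1)
    stop("render_scan renders one region at a time; map over regions")
  if (!is.null(pattern$fov_um)) {
    fov_mm <- fov_diameter(config)$diameter_mm
    if (pattern$fov_um > fov_mm * 1000 + 1e-6)
      stop(sprintf("pattern field (%g um) exceeds the configuration's usable field (%.0f um)",
                   pattern$fov_um, fov_mm * 1000))
  }
  region <- pattern$regions[[1]]
  psf <- psf %||% predict_psf(config)
  sL <- fwhm_to_sigma(psf$lateral_fwhm_um)
  sA <- fwhm_to_sigma(psf$axial_fwhm_um)
  px <- region$pixels_per_line; nl <- region$n_lines
  x_um <- region$x0_um + seq(-region$width_um / 2, region$width_um / 2,
                             length.out = px)
  y_um <- region$y0_um + if (nl > 1)
    seq(-region$height_um / 2, region$height_um / 2, length.out = nl) else 0
  zprof <- profile_z_um(region$zprofile, nl, region$height_um)
  r_mm <- sqrt(outer(y_um^2, x_um^2, `+`)) / 1000
  z_axial <- if (refocus) 0 else focus_solution(config)$focus_point_um[["z"]]
  R <- config$field_sphere_radius_mm
  sag_um <- 1000 * (R - sqrt(pmax(R^2 - r_mm^2, 0)))
  z0 <- z_axial - sag_um + matrix(zprof, nl, px)   # [line, pixel]
  vig <- .vignetting_interp(config, max(r_mm))(r_mm)
  exc2 <- matrix((1 - vig)^2, nl, px)
  tilt_pm <- .tilt_per_mm(config)

  em <- phantom$emitters
  n_frames <- length(stage_z_um)
  out <- array(phantom$background, dim = c(n_frames, nl, px))
  if (!is.null(seed)) set.seed(seed)
  for (f in seq_len(n_frames)) {
    zf <- z0 + stage_z_um[f]
    img <- matrix(phantom$background, nl, px)
    for (e in seq_len(nrow(em))) {
      ss <- em$diameter_um[e] / sqrt(20)
      sLe <- sqrt(sL^2 + ss^2); sAe <- sqrt(sA^2 + ss^2)
      amp <- em$brightness[e] * (sL / sLe)^2 * (sA / sAe)
      if (!is.null(brightness_scale)) amp <- amp * brightness_scale[f, e]
      alpha <- tilt_pm * sqrt(em$x_um[e]^2 + em$y_um[e]^2) / 1000
      b_lat <- 4.5 * (sLe + sAe * abs(sin(alpha)))
      ix <- which(abs(x_um - em$x_um[e]) <= b_lat)
      iy <- which(abs(y_um - em$y_um[e]) <= b_lat)
      if (!length(ix) || !length(iy)) next
      dzmax <- 4.5 * (sAe + sLe * abs(sin(alpha)))
      dz <- em$z_um[e] - zf[iy, ix, drop = FALSE]
      if (all(abs(dz) > dzmax)) next
      dx <- matrix(em$x_um[e] - x_um[ix], length(iy), length(ix), byrow = TRUE)
      dy <- matrix(em$y_um[e] - y_um[iy], length(iy), length(ix))
      if (abs(alpha) > 1e-3) {
        # rotate about the field azimuth of the emitter
        phi <- atan2(em$y_um[e], em$x_um[e])
        dr <- dx * cos(phi) + dy * sin(phi)    # radial component
        dt <- -dx * sin(phi) + dy * cos(phi)   # tangential
        d_ax <- dr * sin(alpha) + dz * cos(alpha)
        d_r  <- dr * cos(alpha) - dz * sin(alpha)
        g <- exp(-d_ax^2 / (2 * sAe^2) - (d_r^2 + dt^2) / (2 * sLe^2))
      } else {
        g <- exp(-(dx^2 + dy^2) / (2 * sLe^2) - dz^2 / (2 * sAe^2))
      }
      img[iy, ix] <- img[iy, ix] + amp * g * exc2[iy, ix, drop = FALSE]
    }
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
    out[f, , ] <- img
  }
  structure(list(pixels = out, x_um = x_um, y_um = y_um,
                 stage_z_um = stage_z_um,
                 pixel_size_um = c(x = if (px > 1) diff(x_um[1:2]) else region$width_um,
                                   y = if (nl > 1) diff(y_um[1:2]) else region$height_um),
                 z_step_um = if (n_frames > 1) diff(stage_z_um[1:2]) else NA_real_,
                 focus_z_um = z0,
                 psf = psf,
                 provenance = list(preset = config$preset,
                                   lens_distance_mm = config$lens_distance_mm,
                                   pattern_hash = .pattern_hash(pattern),
                                   phantom_seed = phantom$seed,
                                   noise_seed = seed)),
            class = "ntc_acquired")
}

#' @export
print.ntc_acquired <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<ntc_acquired> %d frame(s) x %d lines x %d px (%.3f x %.3f um/px)\n",
              d[1], d[2], d[3], x$pixel_size_um["x"], x$pixel_size_um["y"]))
  invisible(x)
}

#' Render a bead z-stack following the PSF measurement protocol
#'
#' Defaults mirror the bead protocol: 30 x 30 um field, 256 x 256 px
#' (0.117 um/px) and 0.5 um axial steps.  The axial range covers the
#' emitters' z spread plus `z_pad_fwhm` axial FWHMs of the model PSF.
#'
#' @param config An [optical_config()].
#' @param phantom Bead phantom.
#' @param fov_um Lateral field, um.
#' @param px Pixels per line (and lines).
#' @param z_step_um Axial step, um.
#' @param z_pad_fwhm Padding beyond the emitter z-range, in axial FWHMs.
#' @param psf,noise_sd,seed Passed to [render_scan()].
#' @return An `ntc_acquired` stack.
#' @export
render_bead_stack <- function(config, phantom, fov_um = 30, px = 256,
                              z_step_um = 0.5, z_pad_fwhm = 2,
                              psf = NULL, noise_sd = 0, seed = NULL) {
  psf <- psf %||% predict_psf(config)
  pad <- z_pad_fwhm * psf$axial_fwhm_um
  zr <- range(phantom$emitters$z_um)
  stage <- seq(zr[1] - pad, zr[2] + pad, by = z_step_um)
  pat <- build_raster(px, px, line_period_ms = 1, extent_um = fov_um)
  render_scan(config, pat, phantom, stage_z_um = stage, psf = psf,
              noise_sd = noise_sd, seed = seed)
}

#' Side-view (x-z) projection of the excitation during a scan
#'
#' Emulates filming a dye-filled cuvette from the side: the squared-intensity
#' excitation profile of every scan point along the central line is
#' accumulated on an x-z grid, making scan-plane curvature, z-profiles and
#' the outward tilt of edge foci directly visible.
#'
#' @param config An [optical_config()].
#' @param pattern An `ntc_pattern`; scan points are taken along the fast axis
#'   of each region at its central line, with the region z-profile sampled
#'   across lines mapped onto x for display of staircase/halfpipe paths.
#' @param n_scan Scan points per region.
#' @param nx,nz Grid size.
#' @param z_range_um Optional c(min, max) of the grid (um, relative to the
#'   nominal focal plane).
#' @return List with `image` `[nz, nx]`, `x_um`, `z_um`.
#' @export
render_side_profile <- function(config, pattern, n_scan = 65,
                                nx = 240, nz = 160, z_range_um = NULL) {
  psf <- predict_psf(config)
  sL <- fwhm_to_sigma(psf$lateral_fwhm_um)
  sA <- fwhm_to_sigma(psf$axial_fwhm_um)
  R <- config$field_sphere_radius_mm
  tilt_pm <- .tilt_per_mm(config)
  pts <- do.call(rbind, lapply(pattern$regions, function(r) {
    xs <- r$x0_um + seq(-r$width_um / 2, r$width_um / 2, length.out = n_scan)
    zp <- profile_z_um(r$zprofile, n_scan, r$height_um)
    data.frame(x = xs, zp = zp)
  }))
  r_mm <- abs(pts$x) / 1000
  sag <- 1000 * (R - sqrt(pmax(R^2 - r_mm^2, 0)))
  pts$z <- -sag + pts$zp   # relative to the on-axis focus
  pts$alpha <- tilt_pm * r_mm
  xr <- range(pts$x) + c(-1, 1) * 4 * sL
  if (is.null(z_range_um))
    z_range_um <- range(pts$z) + c(-1, 1) * 3 * sA
  xg <- seq(xr[1], xr[2], length.out = nx)
  zg <- seq(z_range_um[1], z_range_um[2], length.out = nz)
  img <- matrix(0, nz, nx)
  dxm <- outer(rep(1, nz), xg)
  dzm <- outer(zg, rep(1, nx))
  for (i in seq_len(nrow(pts))) {
    dx <- dxm - pts$x[i]; dz <- dzm - pts$z[i]
    a <- pts$alpha[i] * sign(pts$x[i])
    d_ax <- dx * sin(a) + dz * cos(a)
    d_lat <- dx * cos(a) - dz * sin(a)
    img <- img + exp(-d_ax^2 / (2 * sA^2) - d_lat^2 / (2 * sL^2))
  }
  list(image = img, x_um = xg, z_um = zg)
}

#' Render an activity movie
#'
#' Emitter brightness is modulated by kernel-convolved event trains from the
#' [activity_model()]; the static spatial footprint of each emitter is
#' rendered once and scaled per frame.
#'
#' @param config,pattern,phantom As in [render_scan()].
#' @param activity An [activity_model()].
#' @param n_frames Number of frames.
#' @param seed RNG seed (event draws and noise).
#' @return An `ntc_acquired` movie with `frame_times_s` and
#'   `emitter_traces` attached.
#' @export
render_timeseries <- function(config, pattern, phantom, activity,
                              n_frames = 50, seed = 1) {
  tr <- timing_report(pattern)
  frame_times <- (seq_len(n_frames) - 1) * tr$cycle_duration_ms / 1000
  set.seed(seed)
  traces <- .activity_traces(activity, nrow(phantom$emitters), frame_times)
  traces <- matrix(traces, nrow = n_frames)
  acq <- render_scan(config, pattern, phantom,
                     stage_z_um = rep(0, n_frames),
                     brightness_scale = traces,
                     noise_sd = activity$noise_sd, seed = seed + 1)
  acq$frame_times_s <- frame_times
  acq$emitter_traces <- traces
  acq$provenance$activity_seed <- seed
  acq
}
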