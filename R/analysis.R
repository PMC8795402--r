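# Measurement procedures: FWHM fits, bead-stack PSF estimation, radial
# brightness, neighbour-correlation activity maps, z-scored traces and
# event-triggered averages.

#' Gaussian fit of a 1-D intensity profile with FWHM
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - centre)^2 / (2
#' sigma^2))`; the FWHM is `2 sqrt(2 ln 2) sigma`.  A constant or
#' non-converging profile yields an explicit failure result (`converged =
#' FALSE`, `fwhm_um = NA`), never a silent number.
#'
#' @param x Coordinates (um).
#' @param y Intensities.
#' @return An object of class `ntc_fwhm_fit`: list with `fwhm_um`,
#'   `centre_um`, `amplitude`, `offset`, `sigma_um`, `r_squared`,
#'   `converged`.
#' @export
gaussian_fwhm_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 5) stop("need at least 5 samples")
  fail <- structure(list(fwhm_um = NA_real_, centre_um = NA_real_,
                         amplitude = NA_real_, offset = NA_real_,
                         sigma_um = NA_real_, r_squared = NA_real_,
                         converged = FALSE), class = "ntc_fwhm_fit")
  if (stats::sd(y) == 0) return(fail)
  off0 <- min(y); a0 <- max(y) - off0
  mu0 <- x[which.max(y)]
  above <- x[y - off0 > a0 / 2]
  s0 <- max(diff(range(above)) / 2.355, diff(range(x)) / 50, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ off + a * exp(-(x - mu)^2 / (2 * sig^2)),
                      start = list(off = off0, a = a0, mu = mu0, sig = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  if (!is.finite(cf["sig"]) || cf["a"] <= 0) return(fail)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(fwhm_um = sigma_to_fwhm(abs(cf[["sig"]])),
                 centre_um = cf[["mu"]], amplitude = cf[["a"]],
                 offset = cf[["off"]], sigma_um = abs(cf[["sig"]]),
                 r_squared = 1 - ss_res / ss_tot,
                 converged = TRUE), class = "ntc_fwhm_fit")
}

#' @export
print.ntc_fwhm_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<ntc_fwhm_fit> FWHM %.4g um (centre %.4g, R^2 %.4f)\n",
                x$fwhm_um, x$centre_um, x$r_squared))
  else cat("<ntc_fwhm_fit> fit failed\n")
  invisible(x)
}

# Local maxima of a 3D stack [z, y, x] above a threshold.
.find_beads <- function(arr, threshold) {
  d <- dim(arr)
  idx <- which(arr > threshold, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    z <- idx[i, 1]; y <- idx[i, 2]; x <- idx[i, 3]
    nb <- arr[max(1, z - 1):min(d[1], z + 1),
              max(1, y - 1):min(d[2], y + 1),
              max(1, x - 1):min(d[3], x + 1)]
    keep[i] <- arr[z, y, x] >= max(nb)
  }
  idx <- idx[keep, , drop = FALSE]
  # deduplicate plateau maxima closer than 3 voxels
  if (nrow(idx) > 1) {
    ord <- order(-arr[idx])
    idx <- idx[ord, , drop = FALSE]
    sel <- rep(TRUE, nrow(idx))
    for (i in seq_len(nrow(idx))[-1])
      for (j in seq_len(i - 1))
        if (sel[j] && all(abs(idx[i, ] - idx[j, ]) < 3)) { sel[i] <- FALSE; break }
    idx <- idx[sel, , drop = FALSE]
  }
  idx
}

#' Estimate the PSF from a rendered (or loaded) bead stack
#'
#' Detects beads as local maxima above `background mean + threshold_sd *
#' background s.d.`, extracts x, y and z intensity profiles through each
#' bead's maximum, fits them with [gaussian_fwhm_fit()], and aggregates
#' per-bead lateral (mean of x and y) and axial FWHMs as mean +/- s.d.
#' Beads whose fit window would cross the stack border, and beads with
#' another bead close enough to contaminate their profiles, are excluded
#' rather than mis-fit (the measurement protocol uses isolated beads).
#'
#' @param stack An `ntc_acquired` z-stack, or a plain 3D array `[z, y, x]`
#'   with attributes/arguments giving the pixel sizes.
#' @param threshold_sd Detection threshold in background s.d. units.
#' @param pixel_size_um Lateral pixel size (um); taken from the stack when
#'   available.
#' @param z_step_um Axial step (um); taken from the stack when available.
#' @param window_fwhm Fit window half-width in units of a first-guess FWHM
#'   (1.5 FWHM = +/- 3.5 sigma).
#' @return An object of class `ntc_psf_estimate`: list with
#'   `lateral_fwhm_um`, `axial_fwhm_um` (means), `lateral_sd_um`,
#'   `axial_sd_um`, `n_beads`, and the per-bead table `beads`.
#' @export
psf_from_beadstack <- function(stack, threshold_sd = 8,
                               pixel_size_um = NULL, z_step_um = NULL,
                               window_fwhm = 1.5) {
  if (inherits(stack, "ntc_acquired")) {
    arr <- aperm(stack$pixels, c(1, 2, 3))   # [frame(z), line(y), pixel(x)]
    pixel_size_um <- pixel_size_um %||% unname(stack$pixel_size_um["x"])
    z_step_um <- z_step_um %||% stack$z_step_um
  } else arr <- stack
  if (is.null(pixel_size_um) || is.null(z_step_um) || is.na(z_step_um))
    stop("pixel_size_um and z_step_um required")
  d <- dim(arr)
  if (d[1] < 3) stop("stack needs at least 3 z-planes")
  bg <- stats::median(arr)
  bg_sd <- stats::sd(arr[arr <= stats::quantile(arr, 0.9)])
  thr <- bg + threshold_sd * max(bg_sd, 1e-12)
  peaks <- .find_beads(arr, thr)
  if (nrow(peaks) == 0) stop("no beads detected above threshold")
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    z <- peaks[i, 1]; y <- peaks[i, 2]; x <- peaks[i, 3]
    # width guess: contiguous above-half-max run through the peak itself
    prof_fwhm <- function(v, peak_idx, step) {
      above <- v - bg > (v[peak_idx] - bg) / 2
      lo <- peak_idx; while (lo > 1 && above[lo - 1]) lo <- lo - 1
      hi <- peak_idx; while (hi < length(v) && above[hi + 1]) hi <- hi + 1
      max((hi - lo + 1) * step, step)
    }
    wlat <- prof_fwhm(arr[z, y, ], x, pixel_size_um)
    wax <- prof_fwhm(arr[, y, x], z, z_step_um)
    # isolation: another detected bead within the profile footprint spoils
    # the 1-D fits
    if (nrow(peaks) > 1) {
      dlat <- sqrt(((peaks[, 3] - x) * pixel_size_um)^2 +
                     ((peaks[, 2] - y) * pixel_size_um)^2)
      dax <- abs(peaks[, 1] - z) * z_step_um
      near <- dlat < 3 * wlat & dax < 3 * wax
      if (sum(near) > 1) next
    }
    hx <- ceiling(window_fwhm * wlat / pixel_size_um)
    hz <- ceiling(window_fwhm * wax / z_step_um)
    if (x - hx < 1 || x + hx > d[3] || y - hx < 1 || y + hx > d[2] ||
        z - hz < 1 || z + hz > d[1]) next  # border bead: exclude
    xi <- (x - hx):(x + hx); yi <- (y - hx):(y + hx); zi <- (z - hz):(z + hz)
    fx <- gaussian_fwhm_fit(xi * pixel_size_um, arr[z, y, xi])
    fy <- gaussian_fwhm_fit(yi * pixel_size_um, arr[z, yi, x])
    fz <- gaussian_fwhm_fit(zi * z_step_um, arr[zi, y, x])
    if (!fx$converged || !fy$converged || !fz$converged) next
    rows[[length(rows) + 1L]] <- data.frame(
      x_px = x, y_px = y, z_plane = z,
      lateral_fwhm_um = (fx$fwhm_um + fy$fwhm_um) / 2,
      axial_fwhm_um = fz$fwhm_um)
  }
  if (!length(rows)) stop("no beads could be fit away from the stack border")
  beads <- do.call(rbind, rows)
  structure(list(lateral_fwhm_um = mean(beads$lateral_fwhm_um),
                 axial_fwhm_um = mean(beads$axial_fwhm_um),
                 lateral_sd_um = stats::sd(beads$lateral_fwhm_um),
                 axial_sd_um = stats::sd(beads$axial_fwhm_um),
                 n_beads = nrow(beads), beads = beads),
            class = "ntc_psf_estimate")
}

#' @export
print.ntc_psf_estimate <- function(x, ...) {
  cat(sprintf("<ntc_psf_estimate> lateral %.3f +/- %.3f um, axial %.3f +/- %.3f um (n = %d)\n",
              x$lateral_fwhm_um, x$lateral_sd_um %||% NA,
              x$axial_fwhm_um, x$axial_sd_um %||% NA, x$n_beads))
  invisible(x)
}

#' Mean brightness versus radius
#'
#' Annulus means from the image centre out to the inscribed-circle edge.
#'
#' @param image 2D matrix.
#' @param bin_width_px Annulus width, pixels.
#' @param center c(row, col); defaults to the image centre.
#' @return data.frame with `radius_px` (bin centre) and `mean_brightness`.
#' @export
radial_brightness <- function(image, bin_width_px = 1, center = NULL) {
  if (length(dim(image)) != 2) stop("image must be 2D")
  d <- dim(image)
  ctr <- center %||% ((d + 1) / 2)
  r <- sqrt(outer((seq_len(d[1]) - ctr[1])^2, (seq_len(d[2]) - ctr[2])^2, `+`))
  rmax <- min(d - 1) / 2
  bins <- seq(0, rmax + bin_width_px, by = bin_width_px)
  cut_i <- findInterval(r, bins, rightmost.closed = TRUE)
  ok <- r <= rmax
  m <- tapply(image[ok], cut_i[ok], mean)
  data.frame(radius_px = bins[as.integer(names(m))] + bin_width_px / 2,
             mean_brightness = as.numeric(m))
}

#' Neighbour-correlation activity map
#'
#' For each pixel, the mean Pearson correlation of its time series with each
#' of its 4- or 8-connected neighbours.  Zero-variance pixels map to 0 by
#' convention.  The map is invariant to per-pixel affine intensity rescaling
#' and bounded in [-1, 1].
#'
#' @param movie 3D array `[frame, y, x]` or an `ntc_acquired` movie.
#' @param neighbourhood 4 or 8.
#' @return Matrix `[y, x]` of mean neighbour correlations.
#' @export
activity_correlation <- function(movie, neighbourhood = 8) {
  if (inherits(movie, "ntc_acquired")) movie <- movie$pixels
  if (!neighbourhood %in% c(4, 8)) stop("neighbourhood must be 4 or 8")
  d <- dim(movie)
  if (d[1] < 3) stop("need at least 3 frames")
  nt <- d[1]; ny <- d[2]; nx <- d[3]
  mu <- apply(movie, c(2, 3), mean)
  cen <- sweep(movie, c(2, 3), mu)
  sdv <- sqrt(apply(cen^2, c(2, 3), sum))
  zden <- ifelse(sdv > 0, sdv, Inf)
  zn <- sweep(cen, c(2, 3), zden, "/")
  shifts <- if (neighbourhood == 4)
    list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  else
    list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  acc <- matrix(0, ny, nx); cnt <- matrix(0, ny, nx)
  for (s in shifts) {
    dy <- s[1]; dx <- s[2]
    y1 <- max(1, 1 + dy):min(ny, ny + dy)
    x1 <- max(1, 1 + dx):min(nx, nx + dx)
    y0 <- y1 - dy; x0 <- x1 - dx
    cc <- apply(zn[, y1, x1, drop = FALSE] * zn[, y0, x0, drop = FALSE],
                c(2, 3), sum)
    acc[y0, x0] <- acc[y0, x0] + cc
    cnt[y0, x0] <- cnt[y0, x0] + 1
  }
  out <- acc / cnt
  out[sdv == 0] <- 0
  pmin(pmax(out, -1), 1)
}

#' ROI traces: z-scores and event-triggered averages
#'
#' Each ROI's trace is the mean over its pixels per frame.  Z-scores are
#' computed against the ROI's own baseline window (`(x - mean_b) / sd_b`);
#' the event-triggered average aligns fixed windows on the event frames and
#' averages across trials.
#'
#' @param movie 3D array `[frame, y, x]` or `ntc_acquired`.
#' @param rois List of ROI definitions: logical masks `[y, x]` or 2-column
#'   matrices of (y, x) pixel indices.
#' @param baseline_frames Integer vector of baseline frame indices.
#' @param event_frames Integer vector of event-onset frames (optional).
#' @param window_frames c(pre, post) window around each event, frames.
#' @return An object of class `ntc_traces`: list with `raw` (frames x ROIs),
#'   `zscored`, `eta` (window x ROIs, or NULL), `n_trials`,
#'   `baseline_frames`, `eta_offsets`.
#' @export
trace_stats <- function(movie, rois, baseline_frames,
                        event_frames = NULL, window_frames = c(2, 10)) {
  if (inherits(movie, "ntc_acquired")) movie <- movie$pixels
  d <- dim(movie)
  if (!length(baseline_frames)) stop("baseline window is empty")
  if (any(baseline_frames < 1 | baseline_frames > d[1]))
    stop("baseline window outside the movie")
  raw <- sapply(rois, function(roi) {
    if (is.logical(roi)) {
      if (!all(dim(roi) == d[2:3])) stop("ROI mask dimensions mismatch")
      idx <- which(roi, arr.ind = TRUE)
    } else idx <- roi
    if (any(idx[, 1] > d[2]) || any(idx[, 2] > d[3]))
      stop("ROI outside the frame")
    flat <- (idx[, 2] - 1) * d[2] + idx[, 1]
    apply(movie, 1, function(fr) mean(fr[flat]))
  })
  raw <- matrix(raw, nrow = d[1])
  mu_b <- colMeans(raw[baseline_frames, , drop = FALSE])
  sd_b <- apply(raw[baseline_frames, , drop = FALSE], 2, stats::sd)
  if (any(sd_b == 0)) stop("zero baseline variance in ROI(s): ",
                           paste(which(sd_b == 0), collapse = ", "))
  z <- sweep(sweep(raw, 2, mu_b), 2, sd_b, "/")
  eta <- NULL; n_trials <- 0L; offs <- NULL
  if (!is.null(event_frames) && length(event_frames)) {
    offs <- (-window_frames[1]):(window_frames[2])
    ok <- event_frames[event_frames + min(offs) >= 1 &
                         event_frames + max(offs) <= d[1]]
    n_trials <- length(ok)
    if (n_trials > 0) {
      eta <- matrix(0, length(offs), ncol(z))
      for (ev in ok) eta <- eta + z[ev + offs, , drop = FALSE]
      eta <- eta / n_trials
    }
  }
  structure(list(raw = raw, zscored = z, eta = eta, n_trials = n_trials,
                 baseline_frames = baseline_frames, eta_offsets = offs),
            class = "ntc_traces")
}
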