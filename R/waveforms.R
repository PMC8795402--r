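# Line-synchronized command waveforms: galvos, ETL, Pockels.

#' Emit command waveforms for a scan pattern
#'
#' Scanning is unidirectional: the fast-axis ramp occupies
#' `1 - turnaround_fraction` of each line and flies back during the
#' turnaround, over which the Pockels transmission is blanked to zero.
#' Transition lines between random-access regions are fully blanked.  The
#' ETL command is piecewise constant per line (the device receives one
#' command per line tick).
#'
#' @param pattern An `ntc_pattern`.
#' @param sample_rate_hz Output sample rate, Hz; must give at least 2
#'   samples per line.
#' @param turnaround_fraction Fraction of each line spent on the fast-axis
#'   turnaround (blanked), in `[0, 0.5]`.
#' @param etl_calibration Passed to [apply_z_profile()]; `NULL` keeps the
#'   ETL channel in um of commanded displacement.
#' @return An object of class `ntc_waveforms`: list with `sample_rate_hz`,
#'   per-sample numeric vectors `x`, `y`, `etl`, `pockels`, the per-line
#'   sample index table `lines` (`start`, `end`, `type`, `region`, `line`),
#'   and `samples_per_line`.
#' @export
emit_waveforms <- function(pattern, sample_rate_hz = 100e3,
                           turnaround_fraction = 0.1,
                           etl_calibration = NULL) {
  if (turnaround_fraction < 0 || turnaround_fraction > 0.5)
    stop("turnaround_fraction must be in [0, 0.5]")
  periods <- vapply(pattern$regions, `[[`, numeric(1), "line_period_ms")
  spl <- round(sample_rate_hz * periods[1] / 1000)
  if (any(abs(periods - periods[1]) > 1e-12))
    stop("emit_waveforms requires a common line period across regions")
  if (spl < 2) stop("sample rate too low: need >= 2 samples per line")
  n_reg <- length(pattern$regions)
  trans <- if (n_reg > 1) pattern$transition_lines else 0L

  n_active <- max(2, round(spl * (1 - turnaround_fraction)))
  if (n_active >= spl && turnaround_fraction > 0) n_active <- spl - 1

  line_list <- list()
  for (ri in seq_len(n_reg)) {
    r <- pattern$regions[[ri]]
    zcmd <- apply_z_profile(r, etl_calibration = etl_calibration)
    etl_line <- if (!is.null(etl_calibration)) zcmd$etl_dpt else zcmd$z_um
    yy <- if (r$n_lines > 1)
      seq(-1, 1, length.out = r$n_lines) else 0
    for (li in seq_len(r$n_lines))
      line_list[[length(line_list) + 1L]] <-
        list(type = "active", region = ri, line = li,
             y = yy[li], etl = etl_line[li],
             x0 = r$x0_um, w = r$width_um)
    if (trans > 0)
      for (ti in seq_len(trans))
        line_list[[length(line_list) + 1L]] <-
          list(type = "transition", region = ri, line = NA_integer_,
               y = yy[length(yy)], etl = etl_line[r$n_lines],
               x0 = r$x0_um, w = r$width_um)
  }
  n_lines_total <- length(line_list)
  n_samples <- n_lines_total * spl
  x <- numeric(n_samples); y <- numeric(n_samples)
  etl <- numeric(n_samples); pockels <- numeric(n_samples)
  ramp <- c(seq(-1, 1, length.out = n_active),
            seq(1, -1, length.out = spl - n_active + 1)[-1])
  lines <- data.frame(start = integer(n_lines_total),
                      end = integer(n_lines_total),
                      type = character(n_lines_total),
                      region = integer(n_lines_total),
                      line = integer(n_lines_total),
                      stringsAsFactors = FALSE)
  for (k in seq_len(n_lines_total)) {
    li <- line_list[[k]]
    idx <- ((k - 1) * spl + 1):(k * spl)
    x[idx] <- ramp
    y[idx] <- li$y
    etl[idx] <- li$etl
    pockels[idx] <- if (li$type == "active")
      c(rep(1, n_active), rep(0, spl - n_active)) else 0
    lines$start[k] <- idx[1]; lines$end[k] <- idx[length(idx)]
    lines$type[k] <- li$type; lines$region[k] <- li$region
    lines$line[k] <- li$line
  }
  structure(list(sample_rate_hz = sample_rate_hz,
                 samples_per_line = spl,
                 active_samples_per_line = n_active,
                 turnaround_fraction = turnaround_fraction,
                 x = x, y = y, etl = etl, pockels = pockels,
                 lines = lines), class = "ntc_waveforms")
}

#' @export
print.ntc_waveforms <- function(x, ...) {
  cat(sprintf("<ntc_waveforms> %d lines x %d samples @ %.0f Hz (%d active samples/line)\n",
              nrow(x$lines), x$samples_per_line, x$sample_rate_hz,
              x$active_samples_per_line))
  invisible(x)
}

#' Write waveforms as CSV
#'
#' One column per channel plus a `line` index column; the sample rate is
#' recorded in a `#`-prefixed header line.
#'
#' @param wf An `ntc_waveforms`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_waveforms_csv <- function(wf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz=%g samples_per_line=%d",
                     wf$sample_rate_hz, wf$samples_per_line), con)
  line_of_sample <- rep(seq_len(nrow(wf$lines)), each = wf$samples_per_line)
  utils::write.csv(data.frame(line = line_of_sample, x = wf$x, y = wf$y,
                              etl = wf$etl, pockels = wf$pockels),
                   con, row.names = FALSE)
  invisible(path)
}

#' ETL settling transient for a commanded axial step
#'
#' The lens is modelled as a linear second-order system (natural frequency
#' and damping ratio from the [etl_model()]); the defaults are set so that a
#' 150 um step settles below a 5 um error within 3 ms, matching the 2-3 ms
#' settling observed for such jumps.
#'
#' @param step_um Commanded axial step, um.
#' @param etl An [etl_model()].
#' @param threshold_um Settling band, um (> 0).
#' @param dt_ms Sampling interval of the returned transient, ms.
#' @param horizon_ms Duration simulated, ms.
#' @return List with `settle_time_ms` (first time after which the error
#'   stays below `threshold_um`), `time_ms`, `position_um`, `step_um`.
#' @export
etl_transient <- function(step_um, etl = etl_model(), threshold_um = 5,
                          dt_ms = 0.002, horizon_ms = 25) {
  if (threshold_um <= 0) stop("threshold_um must be > 0")
  t <- seq(0, horizon_ms, by = dt_ms)
  if (step_um == 0) {
    return(list(settle_time_ms = 0, time_ms = t,
                position_um = rep(0, length(t)), step_um = 0))
  }
  z <- etl$damping_ratio
  wn <- 2 * pi * etl$natural_frequency_hz / 1000   # rad/ms
  y <- if (z < 1) {
    wd <- wn * sqrt(1 - z^2)
    1 - exp(-z * wn * t) * (cos(wd * t) + z / sqrt(1 - z^2) * sin(wd * t))
  } else {
    1 - exp(-wn * t) * (1 + wn * t)
  }
  pos <- step_um * y
  err <- abs(pos - step_um)
  over <- which(err >= threshold_um)
  settle <- if (length(over)) t[max(over)] + dt_ms else 0
  list(settle_time_ms = settle, time_ms = t, position_um = pos,
       step_um = step_um)
}

#' Per-line Pockels scale factors compensating depth-dependent power loss
#'
#' @param pattern An `ntc_pattern`.
#' @param law Function mapping depth (um, the per-line z command) to a
#'   transmission scale in `(0, 1]`.
#' @return List of per-region numeric vectors (one scale per line).
#' @export
depth_power_compensation <- function(pattern, law) {
  lapply(pattern$regions, function(r) {
    z <- profile_z_um(r$zprofile, r$n_lines, r$height_um)
    s <- vapply(z, law, numeric(1))
    if (any(s <= 0 | s > 1))
      stop("power law returned values outside (0, 1]")
    s
  })
}
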