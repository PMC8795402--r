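# Synthetic samples: beads, somata, uniform slabs, activity models.

.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Generate a synthetic phantom
#'
#' Emitters are spheres with preset-typical diameters: `beads` follow the
#' 0.175 +/- 0.005 um fluorescent beads used for PSF protocols;
#' `fly_somata` draw 2-5 um diameters (larval fruit fly, < 5 um),
#' `zebrafish_somata` 5-10 um ("mid-sized"), `mouse_somata` 20-25 um
#' (cortical/subcortical projection neurons, 20+ um); `uniform_slab` lays a
#' dense regular lattice suited to brightness profiling.
#'
#' @param preset One of `"beads"`, `"fly_somata"`, `"zebrafish_somata"`,
#'   `"mouse_somata"`, `"uniform_slab"`.
#' @param n Number of emitters (ignored for `uniform_slab`).
#' @param volume_um Bounding volume, c(x, y, z) extents in um (centred at 0).
#' @param seed RNG seed; recorded in the phantom for reproducibility.
#' @param lattice_spacing_um Emitter spacing for `uniform_slab`.
#' @param brightness Emitter brightness (arbitrary units).
#' @return An object of class `ntc_phantom`: list with `emitters`
#'   (data.frame `x_um`, `y_um`, `z_um`, `diameter_um`, `brightness`, `id`,
#'   `activity_trace_id`), `volume_um`, `background`, `preset`, `seed`.
#' @export
make_phantom <- function(preset = c("beads", "fly_somata", "zebrafish_somata",
                                    "mouse_somata", "uniform_slab"),
                         n = 10, volume_um = c(30, 30, 20), seed = 1,
                         lattice_spacing_um = 5, brightness = 1) {
  preset <- match.arg(preset)
  stopifnot(n >= 0, all(volume_um > 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  half <- volume_um / 2
  if (preset == "uniform_slab") {
    gx <- seq(-half[1], half[1], by = lattice_spacing_um)
    gy <- seq(-half[2], half[2], by = lattice_spacing_um)
    em <- expand.grid(x_um = gx, y_um = gy)
    em$z_um <- 0
    em$diameter_um <- lattice_spacing_um  # contiguous coverage
  } else {
    em <- data.frame(x_um = stats::runif(n, -half[1], half[1]),
                     y_um = stats::runif(n, -half[2], half[2]),
                     z_um = stats::runif(n, -half[3], half[3]))
    em$diameter_um <- switch(preset,
      beads = pmax(stats::rnorm(n, 0.175, 0.005), 0.05),
      fly_somata = stats::runif(n, 2, 5),
      zebrafish_somata = stats::runif(n, 5, 10),
      mouse_somata = stats::runif(n, 20, 25))
  }
  em$brightness <- brightness
  em$id <- seq_len(nrow(em))
  em$activity_trace_id <- NA_integer_
  structure(list(emitters = em, volume_um = volume_um, background = 0,
                 preset = preset, seed = seed), class = "ntc_phantom")
}

#' @export
print.ntc_phantom <- function(x, ...) {
  cat(sprintf("<ntc_phantom> %s: %d emitters in %g x %g x %g um (seed %d)\n",
              x$preset, nrow(x$emitters), x$volume_um[1], x$volume_um[2],
              x$volume_um[3], x$seed))
  invisible(x)
}

#' Calcium-like activity model
#'
#' Events (stimulus-locked, with per-emitter response probability, plus an
#' optional spontaneous Poisson rate) are convolved with an
#' instantaneous-rise, exponential-decay calcium kernel and scale emitter
#' brightness multiplicatively.
#'
#' @param event_rate_hz Spontaneous event rate, Hz.
#' @param stimulus_times_s Stimulus onset times, s.
#' @param response_prob Per-stimulus response probability in `[0, 1]`.
#' @param tau_s Decay time constant, s (> 0); default 0.7 s, in the range of
#'   a fast genetically encoded calcium indicator.
#' @param amplitude Multiplicative response amplitude (dF/F-like units).
#' @param noise_sd Additive Gaussian noise s.d. on rendered pixels.
#' @return An object of class `ntc_activity`.
#' @export
activity_model <- function(event_rate_hz = 0, stimulus_times_s = numeric(0),
                           response_prob = 1, tau_s = 0.7, amplitude = 1,
                           noise_sd = 0) {
  if (tau_s <= 0) stop("tau_s must be > 0")
  if (response_prob < 0 || response_prob > 1)
    stop("response_prob must be in [0, 1]")
  structure(list(event_rate_hz = event_rate_hz,
                 stimulus_times_s = stimulus_times_s,
                 response_prob = response_prob,
                 tau_s = tau_s, amplitude = amplitude,
                 noise_sd = noise_sd), class = "ntc_activity")
}

# Per-emitter brightness modulation factors over frame times.
.activity_traces <- function(activity, n_emitters, frame_times_s) {
  sapply(seq_len(n_emitters), function(e) {
    ev <- numeric(0)
    if (length(activity$stimulus_times_s))
      ev <- activity$stimulus_times_s[
        stats::runif(length(activity$stimulus_times_s)) <= activity$response_prob]
    if (activity$event_rate_hz > 0) {
      horizon <- max(frame_times_s)
      k <- stats::rpois(1, activity$event_rate_hz * horizon)
      ev <- c(ev, sort(stats::runif(k, 0, horizon)))
    }
    tr <- rep(1, length(frame_times_s))
    for (te in ev) {
      dt <- frame_times_s - te
      tr <- tr + activity$amplitude * ifelse(dt >= 0, exp(-dt / activity$tau_s), 0)
    }
    tr
  })
}
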