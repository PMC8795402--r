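test_that("a noiseless Gaussian profile is fit exactly", {
  x <- seq(-5, 5, by = 0.1)
  y <- 2 + 7 * exp(-(x - 0.4)^2 / 2)
  fit <- gaussian_fwhm_fit(x, y)
  expect_true(fit$converged)
  expect_equal(fit$fwhm_um, sigma_to_fwhm(1), tolerance = 1e-6)
  expect_equal(fit$centre_um, 0.4, tolerance = 1e-6)
})

test_that("FWHM recovery survives 5% noise within 3%", {
  set.seed(123)
  x <- seq(-6, 6, by = 0.12)
  y <- exp(-x^2 / (2 * 1.3^2)) + rnorm(length(x), 0, 0.05)
  fit <- gaussian_fwhm_fit(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$fwhm_um - sigma_to_fwhm(1.3)) / sigma_to_fwhm(1.3), 0.03)
})

test_that("fit invariances: amplitude, offset and translation", {
  x <- seq(0, 20, by = 0.2)
  y <- exp(-(x - 8)^2 / (2 * 1.1^2))
  f0 <- gaussian_fwhm_fit(x, y)
  f1 <- gaussian_fwhm_fit(x, 5 + 40 * y)
  f2 <- gaussian_fwhm_fit(x + 100, y)
  expect_equal(f1$fwhm_um, f0$fwhm_um, tolerance = 1e-6)
  expect_equal(f2$fwhm_um, f0$fwhm_um, tolerance = 1e-6)
  expect_equal(f2$centre_um, f0$centre_um + 100, tolerance = 1e-6)
})

test_that("degenerate profiles yield explicit failure, never a number", {
  fit <- gaussian_fwhm_fit(1:10, rep(3, 10))
  expect_false(fit$converged)
  expect_true(is.na(fit$fwhm_um))
  expect_error(gaussian_fwhm_fit(1:3, 1:3), "at least 5")
})

test_that("bead stacks with many beads report the protocol-sized n", {
  cfg <- optical_config("DL")
  ph <- make_phantom("beads", n = 14, volume_um = c(24, 24, 3), seed = 21)
  stack <- render_bead_stack(cfg, ph, fov_um = 30, px = 192, z_step_um = 0.5)
  est <- psf_from_beadstack(stack)
  expect_gte(est$n_beads, 10)
  expect_gte(est$lateral_sd_um, 0)
  expect_error(psf_from_beadstack(stack, threshold_sd = 1e12), "no beads")
})

test_that("beads at the stack border are excluded rather than mis-fit", {
  cfg <- optical_config("DL")
  ph <- make_phantom("beads", n = 1, seed = 1)
  ph$emitters$x_um <- 14.8; ph$emitters$y_um <- 0; ph$emitters$z_um <- 0
  stack <- render_bead_stack(cfg, ph, fov_um = 30, px = 128, z_step_um = 0.5)
  expect_error(psf_from_beadstack(stack), "border")
})

test_that("radial brightness profiles behave on analytic inputs", {
  flat <- matrix(3, 41, 41)
  rb <- radial_brightness(flat)
  expect_true(all(abs(rb$mean_brightness - 3) < 1e-12))

  d <- 81
  r <- sqrt(outer((1:d - 41)^2, (1:d - 41)^2, `+`))
  img <- 10 - 0.1 * r
  rb2 <- radial_brightness(img, bin_width_px = 2)
  expect_equal(rb2$mean_brightness, 10 - 0.1 * rb2$radius_px,
               tolerance = 0.05)
})

test_that("neighbour correlation maps identical traces to 1 and noise to ~0", {
  nt <- 24; ny <- 9; nx <- 9
  tr <- sin(seq(0, 4 * pi, length.out = nt))
  mv <- array(rep(tr, ny * nx), dim = c(nt, ny, nx))
  m <- activity_correlation(mv)
  expect_true(all(abs(m - 1) < 1e-9))

  set.seed(5)
  mvn <- array(rnorm(60 * 12 * 12), dim = c(60, 12, 12))
  mn <- activity_correlation(mvn)
  expect_lt(abs(mean(mn)), 0.05)
  expect_true(all(mn >= -1 & mn <= 1))
  expect_error(activity_correlation(mvn[1:2, , ]), "3 frames")
})

test_that("the correlation map is invariant to per-pixel affine rescaling", {
  set.seed(6)
  mv <- array(rnorm(30 * 6 * 6), dim = c(30, 6, 6))
  gains <- matrix(runif(36, 0.5, 5), 6, 6)
  offs <- matrix(runif(36, -10, 10), 6, 6)
  mv2 <- sweep(sweep(mv, c(2, 3), gains, "*"), c(2, 3), offs, "+")
  expect_equal(activity_correlation(mv), activity_correlation(mv2),
               tolerance = 1e-9)
})

test_that("an active emitter appears as a high-correlation blob", {
  cfg <- optical_config("DL")
  pat <- build_raster(15, 15, 1, extent_um = 12)
  ph <- make_phantom("beads", n = 1, seed = 1)
  ph$emitters$x_um <- 0; ph$emitters$y_um <- 0; ph$emitters$z_um <- 0
  ph$emitters$diameter_um <- 2
  act <- activity_model(stimulus_times_s = seq(0.1, 3, by = 0.3),
                        response_prob = 1, tau_s = 0.1, amplitude = 2,
                        noise_sd = 0.002)
  mv <- render_timeseries(cfg, pat, ph, act, n_frames = 200, seed = 4)
  m <- activity_correlation(mv)
  # the blob is connected and centred on the emitter; at this sampling the
  # emitter footprint spans ~3 px, so the peak pixel correlates near 1 and
  # its 4-neighbours (which average in noise-only pixels) stay well above
  # the background
  expect_gt(m[8, 8], 0.8)
  expect_gt(mean(c(m[7, 8], m[9, 8], m[8, 7], m[8, 9])), 0.4)
  border <- m[c(1, 15), c(1, 15)]
  expect_lt(mean(abs(border)), 0.3)
})

test_that("z-scored traces have unit baseline statistics by construction", {
  set.seed(8)
  mv <- array(rnorm(100 * 4 * 4, mean = 50, sd = 4), dim = c(100, 4, 4))
  roi <- matrix(TRUE, 4, 4)
  ts <- trace_stats(mv, list(roi), baseline_frames = 1:40)
  zb <- ts$zscored[1:40, 1]
  expect_lt(abs(mean(zb)), 1e-9)
  expect_lt(abs(stats::sd(zb) - 1), 1e-9)
})

test_that("event-triggered averages reproduce deterministic responses", {
  nt <- 120
  tr <- rep(0, nt)
  events <- seq(20, 100, by = 20)
  for (ev in events) tr[ev:(ev + 3)] <- tr[ev:(ev + 3)] + c(4, 3, 2, 1)
  tr <- tr + sin(seq_len(nt)) * 1e-3   # nonzero baseline variance
  mv <- array(rep(tr, each = 1), dim = c(nt, 1, 1))
  ts <- trace_stats(mv, list(matrix(TRUE, 1, 1)), baseline_frames = 1:15,
                    event_frames = events, window_frames = c(3, 6))
  expect_equal(ts$n_trials, length(events))
  # the ETA peak equals the single-trial amplitude in baseline-sd units
  single <- (4 - mean(tr[1:15])) / stats::sd(tr[1:15])
  expect_equal(max(ts$eta[, 1]), single, tolerance = 0.01)
})

test_that("trace extraction validates its inputs", {
  mv <- array(rnorm(30), dim = c(30, 1, 1))
  expect_error(trace_stats(mv, list(matrix(TRUE, 1, 1)),
                           baseline_frames = integer(0)), "empty")
  flat <- array(5, dim = c(30, 1, 1))
  expect_error(trace_stats(flat, list(matrix(TRUE, 1, 1)),
                           baseline_frames = 1:10), "zero baseline variance")
})
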