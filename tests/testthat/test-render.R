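cfg_dl <- optical_config("DL")
psf_dl <- predict_psf(cfg_dl)

one_bead <- function(z = 0) {
  p <- make_phantom("beads", n = 1, volume_um = c(1e-6, 1e-6, 1e-6), seed = 1)
  p$emitters$x_um <- 0; p$emitters$y_um <- 0; p$emitters$z_um <- z
  p$emitters$diameter_um <- 1e-4   # effectively a point emitter
  p
}

test_that("a point emitter displaced by half the axial FWHM gives half the peak", {
  pat <- build_raster(41, 41, 1, extent_um = 4)
  at_focus <- render_scan(cfg_dl, pat, one_bead(0))
  displaced <- render_scan(cfg_dl, pat, one_bead(psf_dl$axial_fwhm_um / 2))
  expect_equal(max(displaced$pixels) / max(at_focus$pixels), 0.5,
               tolerance = 1e-3)
})

test_that("lateral phantom translation shifts the image by delta / pixel size", {
  pat <- build_raster(41, 41, 1, extent_um = 20)   # 0.5 um/px
  p0 <- one_bead(); p1 <- one_bead()
  p1$emitters$x_um <- 2                             # 4 px shift
  i0 <- render_scan(cfg_dl, pat, p0)$pixels[1, , ]
  i1 <- render_scan(cfg_dl, pat, p1)$pixels[1, , ]
  expect_equal(i1[, 5:41], i0[, 1:37], tolerance = 1e-6)
})

test_that("the overlap integral converges under pixel refinement", {
  totals <- vapply(c(21, 41, 81), function(px) {
    pat <- build_raster(px, px, 1, extent_um = 6)
    a <- render_scan(cfg_dl, pat, one_bead())
    sum(a$pixels) * prod(a$pixel_size_um)
  }, numeric(1))
  expect_lt(abs(totals[3] - totals[2]) / totals[3], 0.01)
  expect_lt(abs(totals[3] - totals[1]) / totals[3], 0.05)
})

test_that("rendering is deterministic given config, pattern, phantom and seed", {
  pat <- build_raster(16, 16, 1, extent_um = 20)
  ph <- make_phantom("beads", n = 5, volume_um = c(15, 15, 4), seed = 3)
  a <- render_scan(cfg_dl, pat, ph, noise_sd = 0.05, seed = 11)
  b <- render_scan(cfg_dl, pat, ph, noise_sd = 0.05, seed = 11)
  expect_identical(a$pixels, b$pixels)
})

test_that("bead-stack rendering and estimation round-trip the model PSF", {
  ph <- make_phantom("beads", n = 4, volume_um = c(18, 18, 3), seed = 5)
  stack <- render_bead_stack(cfg_dl, ph, fov_um = 30, px = 256,
                             z_step_um = 0.5)
  est <- psf_from_beadstack(stack)
  expect_gte(est$n_beads, 1)
  expect_lt(abs(est$lateral_fwhm_um - psf_dl$lateral_fwhm_um) /
              psf_dl$lateral_fwhm_um, 0.05)
  expect_lt(abs(est$axial_fwhm_um - psf_dl$axial_fwhm_um) /
              psf_dl$axial_fwhm_um, 0.05)
})

test_that("sub-PSF objects dim while PSF-sized objects stay bright", {
  # equal peak fluorophore density: total emitter signal scales with volume
  cfg <- optical_config("nTC2", 5)     # largest excitation volume
  pat <- build_raster(21, 21, 1, extent_um = 60)
  small <- one_bead(); small$emitters$diameter_um <- 0.175
  small$emitters$brightness <- 0.175^3
  soma <- one_bead(); soma$emitters$diameter_um <- 20
  soma$emitters$brightness <- 20^3
  r_small <- max(render_scan(cfg, pat, small)$pixels)
  r_soma <- max(render_scan(cfg, pat, soma)$pixels)
  expect_gt(r_soma / r_small, 5)
  # the soma/bead brightness ratio grows with the excitation volume: it is
  # larger under the big nTC2 spot than under the DL spot
  r_small_dl <- max(render_scan(cfg_dl, pat, small)$pixels)
  r_soma_dl <- max(render_scan(cfg_dl, pat, soma)$pixels)
  expect_gt((r_soma / r_small) / (r_soma_dl / r_small_dl), 1)
})

test_that("a uniform slab renders near-constant brightness with a marginal edge rise", {
  cfg <- optical_config("nTC2", 100)
  fovum <- fov_diameter(cfg)$diameter_mm * 1000
  ph <- make_phantom("uniform_slab", volume_um = c(fovum, fovum, 10),
                     lattice_spacing_um = fovum / 60, seed = 1)
  ph$emitters$z_um <- 0
  pat <- build_raster(61, 61, 1, extent_um = fovum)
  # image the curved focal surface itself: flat sample, so brightness dips
  # only through vignetting and curvature defocus
  img <- render_scan(cfg, pat, ph)$pixels[1, , ]
  rb <- radial_brightness(img, bin_width_px = 4)
  mid <- rb$mean_brightness[rb$radius_px < max(rb$radius_px) / 2]
  expect_lt(stats::sd(mid) / mean(mid), 0.15)
})

test_that("side profiles are thinnest for DL and show staircase structure", {
  pat <- build_raster(33, 33, 1, extent_um = 400)
  thickness <- function(cfg) {
    sp <- render_side_profile(cfg, pat, n_scan = 21, nx = 60, nz = 80)
    prof <- rowSums(sp$image)
    sum(prof > max(prof) / 2) * diff(sp$z_um[1:2])
  }
  expect_lt(thickness(cfg_dl), thickness(optical_config("nTC1", 100)))

  st <- build_raster(33, 33, 1, extent_um = 400,
                     zprofile = z_profile("staircase", jump_line = 17,
                                          dz_um = 120))
  sp <- render_side_profile(cfg_dl, st, n_scan = 33, nx = 60, nz = 100)
  # two axially separated segments: the z-profile of the occupied rows is bimodal
  occ <- which(rowSums(sp$image) > max(rowSums(sp$image)) / 4)
  expect_gt(max(diff(occ)), 5)
})

test_that("activity movies follow the calcium kernel and recover amplitudes", {
  cfg <- cfg_dl
  pat <- build_raster(12, 12, 1, extent_um = 10)
  ph <- one_bead()
  # zero rate, zero noise: all frames identical
  quiet <- activity_model(event_rate_hz = 0, noise_sd = 0)
  mv <- render_timeseries(cfg, pat, ph, quiet, n_frames = 6, seed = 2)
  expect_true(all(apply(mv$pixels, 1, function(f) identical(f, mv$pixels[1, , ]))))

  # a single certain stimulus: peak within one frame of onset, tau decay
  act <- activity_model(stimulus_times_s = 0.05, response_prob = 1,
                        tau_s = 0.2, amplitude = 1, noise_sd = 0)
  mv2 <- render_timeseries(cfg, pat, ph, act, n_frames = 40, seed = 2)
  tr <- mv2$emitter_traces[, 1]
  expect_lt(abs(which.max(tr) - which(mv2$frame_times_s >= 0.05)[1]), 2)
  pk <- which.max(tr)
  dtau <- mv2$frame_times_s - mv2$frame_times_s[pk]
  expect_equal(tr[pk + 5] - 1, (tr[pk] - 1) * exp(-dtau[pk + 5] / 0.2),
               tolerance = 0.05)

  # probability-0.5 responses over repeated trials recover ~half amplitude
  set.seed(9)
  stims <- seq(0.2, 16, by = 0.4)
  act3 <- activity_model(stimulus_times_s = stims,
                         response_prob = 0.5, tau_s = 0.05, amplitude = 1)
  mv3 <- render_timeseries(cfg, pat, ph, act3, n_frames = 1400, seed = 7)
  stim_frames <- vapply(stims, function(s)
    which(mv3$frame_times_s >= s)[1], integer(1))
  resp <- mv3$emitter_traces[stim_frames + 1, 1] -
    mv3$emitter_traces[stim_frames - 1, 1]
  expect_lt(abs(mean(resp > 0.3) - 0.5), 0.15)
})
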