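test_that("the IFP sits where sequential thin-lens arithmetic puts it", {
  # DL: 50 mm after the f = 50 scan lens, collimated after the tube lens
  ifp_dl <- find_ifp(optical_config("DL"))
  expect_equal(ifp_dl$position_mm, 56.6 + 50, tolerance = 1e-9)
  expect_true(ifp_dl$collimated_after_tube_lens)

  # nTC1, L2 100 mm before the tube lens: L1 focuses at the tube lens, so L2
  # sees a virtual object 100 mm downstream -> v = 1/(1/175 + 1/100)
  v <- oracle_thin_lens_image(175, -100)
  ifp1 <- find_ifp(optical_config("nTC1", 100))
  expect_equal(ifp1$rel_tube_lens_mm, (206.6 + v) - 306.6, tolerance = 1e-6)
  expect_lt(ifp1$rel_tube_lens_mm, 0)      # strictly upstream of the tube lens
  expect_false(ifp1$collimated_after_tube_lens)

  # nTC2, L3 100 mm before the tube lens: converging toward 100 mm past the
  # tube lens, refracted to v = 1/(1/200 + 1/100) = 66.7 mm beyond it,
  # upstream of the aperture ring at 95 mm -> divergent at the aperture
  ifp2 <- find_ifp(optical_config("nTC2", 100))
  expect_equal(ifp2$rel_tube_lens_mm, oracle_thin_lens_image(200, -100),
               tolerance = 1e-6)
  expect_gt(ifp2$rel_tube_lens_mm, 0)
})

test_that("focus solutions obey the axial reference and their symmetries", {
  dl <- focus_solution(optical_config("DL"))
  expect_equal(unname(dl$focus_point_um), c(0, 0, 0), tolerance = 1e-6)

  for (p in list(c("nTC1", 100), c("nTC1", 5), c("nTC2", 100), c("nTC2", 5))) {
    cfg <- optical_config(p[1], as.numeric(p[2]))
    fs <- focus_solution(cfg)
    expect_gt(fs$focus_point_um[["z"]], 0)   # beyond the nominal plane
  }

  cfg <- optical_config("nTC2", 40)
  a <- focus_solution(cfg, 2, -1.5)
  b <- focus_solution(cfg, -2, 1.5)
  expect_equal(a$focus_point_um[["x"]], -b$focus_point_um[["x"]],
               tolerance = 1e-9)
  expect_equal(a$focus_point_um[["y"]], -b$focus_point_um[["y"]],
               tolerance = 1e-9)
  expect_equal(a$focus_point_um[["z"]], b$focus_point_um[["z"]],
               tolerance = 1e-9)                 # z even in mirror angle
  expect_error(focus_solution(cfg, 45, 0), "half-angle")
  expect_error(focus_solution(cfg, etl_current_mA = 1e4), "exceeds")
})

test_that("geometric focus matches the brute-force ray fan everywhere", {
  for (p in c("DL", "nTC1", "nTC2")) {
    for (d in seq(5, 100, length.out = 11)) {
      if (p == "DL" && d > 5) break
      cfg <- optical_config(p, d)
      fan <- oracle_ray_fan_focus(p, d, w0 = cfg$input_beam$waist_radius_mm)
      z_pkg <- focus_solution(cfg)$focus_point_um[["z"]] / 1000 +
        1.33 * 8.25
      expect_lt(abs(z_pkg - fan$z_water) / fan$z_water, 1e-9)
      # the Gaussian waist coincides with the geometric focus to well under
      # 0.5% of the focal distance (diffraction focal shift is negligible)
      gw <- ntcsim:::.gaussian_focus(cfg)$z_waist_mm
      expect_lt(abs(gw - fan$z_water) / fan$z_water, 0.005)
    }
  }
})

test_that("effective N.A. saturates at the objective N.A. when the aperture is filled", {
  # DL telescope magnifies 4x: a waist of (aperture radius)/4 at the input
  # arrives collimated at radius a = 8.25 mm, the exact filling condition
  cfg <- optical_config("DL",
                        input_beam = beam_state(waist_radius_mm = 8.25 / 4))
  expect_equal(effective_na(cfg), 1.0, tolerance = 1e-3)
})

test_that("effective N.A. decreases as divergence at the aperture grows", {
  nas <- c(effective_na(optical_config("DL")),
           effective_na(optical_config("nTC1", 100)),
           effective_na(optical_config("nTC1", 5)),
           effective_na(optical_config("nTC2", 100)),
           effective_na(optical_config("nTC2", 5)))
  expect_true(all(diff(nas) < 0))
  expect_true(all(nas > 0 & nas <= 1))
})

test_that("ETL current maps to focal shift through the calibrated gain", {
  cfg <- optical_config("nTC1", 5)
  expect_equal(etl_current_to_focus_shift(cfg, 0), 0)
  expect_equal(etl_current_to_focus_shift(cfg, 50), 600, tolerance = 1e-3)
  shifts <- vapply(seq(0, 50, by = 2.5), function(i)
    etl_current_to_focus_shift(cfg, i), numeric(1))
  expect_true(all(diff(shifts) > 0))     # strictly increasing over 0-50 mA
  expect_error(etl_current_to_focus_shift(cfg, 400), "maximum")
})
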