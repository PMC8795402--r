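test_that("printed activity-scan frame rates fall out of the line timing", {
  rate <- function(n, ms) timing_report(build_raster(n, n, ms))$frame_rate_hz
  expect_equal(rate(256, 1), 3.90625)
  expect_equal(rate(128, 1), 7.8125)
  expect_equal(rate(170, 1), 1000 / 170)
  expect_equal(rate(64, 1), 15.625)
  expect_equal(rate(1024, 2), 1000 / 2048)
})

test_that("a one-line pattern cycles in exactly one line period", {
  tr <- timing_report(build_raster(1, 16, 1))
  expect_equal(tr$cycle_duration_ms, 1)
  expect_equal(tr$frame_rate_hz, 1000)
})

test_that("six staggered planes give the printed volume rate", {
  zp <- z_profile("multiplane", plane_offsets_um = seq(0, 75, by = 15))
  pat <- build_raster(6 * 170, 340, 1, zprofile = zp)
  tr <- timing_report(pat)
  expect_equal(tr$per_plane_rate_hz, 1000 / 1020)
  expect_equal(tr$n_planes, 6)
})

test_that("integer-microsecond timing matches the floating-point path", {
  pat <- build_random_access(list(
    scan_region(128, 256, 1), scan_region(128, 256, 1)))
  tr <- timing_report(pat)
  total_us <- (128 + 2 + 128 + 2) * 1000L
  expect_equal(tr$frame_rate_hz, 1e6 / total_us, tolerance = 1e-12)
  expect_equal(tr$cycle_duration_ms, total_us / 1000)
  expect_equal(tr$transition_duration_ms, 4)
  # active-only rate excludes the transitions
  expect_equal(tr$frame_rate_active_only_hz, 1e6 / (256 * 1000))
})

test_that("a single region degenerates to the raster case", {
  r <- scan_region(64, 64, 1)
  ra <- build_random_access(list(r))
  expect_equal(timing_report(ra)$frame_rate_hz,
               timing_report(build_raster(64, 64, 1))$frame_rate_hz)
  expect_equal(timing_report(ra)$transition_lines_total, 0)
})

test_that("regions outside the configured field are rejected by name", {
  r <- scan_region(64, 64, 1, x0_um = 0, width_um = 1200, height_um = 100)
  expect_error(scan_pattern(list(r), fov_um = 1000), "field of view")
  expect_error(build_raster(64, 64, 1, extent_um = 1200, fov_um = 1000),
               "field of view")
  expect_error(scan_region(64, 64, 0), "line_period_ms")
})

test_that("z-profiles parameterize the documented scan paths", {
  # staircase: exactly two command levels stepping at the jump line
  st <- profile_z_um(z_profile("staircase", jump_line = 33, dz_um = 40), 64)
  expect_equal(sort(unique(st)), c(0, 40))
  expect_equal(which(diff(st) != 0), 32)

  # tilted 45 degrees over 300 um of slow-axis travel -> 300 um of z travel
  ti <- profile_z_um(z_profile("tilted", angle_deg = 45), 128,
                     y_extent_um = 300)
  expect_equal(diff(range(ti)), 300, tolerance = 1e-9)

  # halfpipe: peak at the centre line, zero at the first and last lines
  hp <- profile_z_um(z_profile("halfpipe", peak_um = 100), 101)
  expect_equal(which.max(hp), 51)
  expect_equal(hp[51], 100)
  expect_lt(max(abs(hp[c(1, 101)])), 1e-4)
  # sqrt(cosine) drive: commanded value at quarter phase
  expect_equal(hp[26], 100 * sqrt(cos(pi * 0.25)), tolerance = 1e-9)

  # multiplane: piecewise constant, one block per plane
  mp <- profile_z_um(z_profile("multiplane", plane_offsets_um = c(0, 15, 30)),
                     30)
  expect_equal(unique(rle(mp)$values), c(0, 15, 30))
  expect_true(all(rle(mp)$lengths == 10))
})

test_that("profiles exceeding the ETL range report the overshoot", {
  cfg <- optical_config("nTC1", 5)
  big <- scan_region(32, 32, 1,
                     zprofile = z_profile("flat", offset_um = 1e5))
  expect_error(apply_z_profile(big, etl_calibration = cfg), "um")
  ok <- scan_region(32, 32, 1,
                    zprofile = z_profile("staircase", jump_line = 16,
                                         dz_um = 100))
  cmd <- apply_z_profile(ok, etl_calibration = cfg)
  expect_equal(length(unique(cmd$etl_dpt)), 2)
})
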