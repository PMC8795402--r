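pat2 <- build_random_access(list(
  scan_region(16, 32, 1, zprofile = z_profile("staircase", jump_line = 9,
                                              dz_um = 50)),
  scan_region(16, 32, 1)))
wf <- emit_waveforms(pat2, sample_rate_hz = 50e3)

test_that("sample bookkeeping: total samples = lines x samples per line", {
  expect_equal(length(wf$x), nrow(wf$lines) * wf$samples_per_line)
  expect_equal(nrow(wf$lines), 16 + 2 + 16 + 2)
  expect_equal(wf$samples_per_line, 50)
})

test_that("Pockels blanking covers all turnaround and transition samples", {
  on <- wf$pockels > 0
  for (k in seq_len(nrow(wf$lines))) {
    idx <- wf$lines$start[k]:wf$lines$end[k]
    if (wf$lines$type[k] == "transition") {
      expect_true(all(wf$pockels[idx] == 0))
    } else {
      act <- idx[seq_len(wf$active_samples_per_line)]
      turn <- setdiff(idx, act)
      expect_true(all(wf$pockels[act] == 1))   # 0% of active samples blanked
      expect_true(all(wf$pockels[turn] == 0))  # 100% of turnaround blanked
    }
  }
  expect_true(all(which(on) %in% unlist(mapply(
    function(s, e) s:e,
    wf$lines$start[wf$lines$type == "active"],
    wf$lines$end[wf$lines$type == "active"], SIMPLIFY = FALSE))))
})

test_that("the ETL command only changes at line boundaries", {
  for (k in seq_len(nrow(wf$lines))) {
    idx <- wf$lines$start[k]:wf$lines$end[k]
    expect_equal(length(unique(wf$etl[idx])), 1)
  }
  # the staircase appears as exactly two command levels in region 1
  expect_equal(length(unique(wf$etl[seq_len(16 * 50)])), 2)
})

test_that("waveform duration equals the timing report exactly", {
  tr <- timing_report(pat2)
  dur_wf_ms <- length(wf$x) / wf$sample_rate_hz * 1000
  expect_equal(dur_wf_ms, tr$cycle_duration_ms, tolerance = 1e-12)
})

test_that("a halfpipe drive peaks at the centre line", {
  hp <- build_raster(64, 32, 1,
                     zprofile = z_profile("halfpipe", peak_um = 100))
  w <- emit_waveforms(hp, 32e3)
  peak_line <- which.max(vapply(seq_len(nrow(w$lines)), function(k)
    w$etl[w$lines$start[k]], numeric(1)))
  expect_true(abs(peak_line - 32.5) <= 1)
})

test_that("degenerate sampling is refused", {
  expect_error(emit_waveforms(pat2, sample_rate_hz = 1000), "sample rate")
})

test_that("the ETL settles a 150 um step within 3 ms at a 5 um band", {
  tr <- etl_transient(150)
  expect_lte(tr$settle_time_ms, 3)
  expect_gt(tr$settle_time_ms, 0.2)
  expect_equal(etl_transient(0)$settle_time_ms, 0)
  # converges to the commanded value
  expect_lt(abs(tr$position_um[length(tr$position_um)] - 150), 150 * 1e-9)
})

test_that("settling time is non-decreasing in step size", {
  steps <- c(10, 50, 100, 150, 300, 600)
  st <- vapply(steps, function(s) etl_transient(s)$settle_time_ms, numeric(1))
  expect_true(all(diff(st) >= 0))
})

test_that("settling converges for any damping ratio in (0, 1]", {
  for (z in c(0.2, 0.5, 0.7, 1.0)) {
    tr <- etl_transient(150, etl_model(damping_ratio = z), horizon_ms = 60)
    final <- tr$position_um[length(tr$position_um)]
    expect_lt(abs(final - 150) / 150, 1e-9)
  }
})

test_that("depth power compensation maps z-profiles to per-line scales", {
  flat <- build_raster(16, 16, 1)
  s <- depth_power_compensation(flat, function(z) 1)[[1]]
  expect_true(all(s == 1))

  st <- build_raster(16, 16, 1,
                     zprofile = z_profile("staircase", jump_line = 9,
                                          dz_um = 100))
  s2 <- depth_power_compensation(st, function(z) exp(-z / 500))[[1]]
  expect_equal(length(unique(s2)), 2)

  hp <- build_raster(33, 16, 1,
                     zprofile = z_profile("halfpipe", peak_um = 100))
  # law increasing with depth: minimum scale on the shallowest lines
  law <- function(z) 0.5 + 0.4 * z / 100
  s3 <- depth_power_compensation(hp, law)[[1]]
  expect_equal(which.min(s3) %in% c(1, 33), TRUE)
  expect_error(depth_power_compensation(hp, function(z) 1.5), "outside")
})
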