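test_that("the alpha band-pass keeps 10 Hz, rejects 20 Hz and removes DC", {
  fs <- 128
  rec10 <- sinusoid_recording(10, 1, 10)
  out10 <- bandpass(rec10, 8, 12)
  keep <- (fs + 1):(nrow(rec10) - fs) # discard 1 s edges
  rms_in <- sqrt(mean(as.data.frame(rec10)$F3[keep]^2))
  rms_out <- sqrt(mean(as.data.frame(out10)$F3[keep]^2))
  expect_lt(abs(rms_out - rms_in) / rms_in, 0.02)

  rec20 <- sinusoid_recording(20, 1, 10)
  out20 <- bandpass(rec20, 8, 12)
  rms20 <- sqrt(mean(as.data.frame(out20)$F3[keep]^2))
  expect_lt(rms20 / rms_in, 0.05)

  dc <- eeg_recording(matrix(7, 1280, 14))
  for (band in c("alpha", "beta")) {
    edges <- band_edges(band)
    filt <- bandpass(dc, edges[1], edges[2])
    expect_lt(abs(mean(as.data.frame(filt)$AF3[keep])), 1e-3)
  }
  expect_error(bandpass(rec10, 8, 70), "Nyquist")
  expect_error(bandpass(rec10, 12, 8), "below")
})

test_that("the filter is linear", {
  sched <- short_schedule(seed = 8)
  rec <- generate_recording(head(sched, 2), noise = noise_spec(5), seed = 8)
  scaled <- eeg_recording(eegaffect:::eeg_matrix(rec) * 3.7)
  f1 <- eegaffect:::eeg_matrix(bandpass(rec, 8, 12))
  f2 <- eegaffect:::eeg_matrix(bandpass(scaled, 8, 12))
  expect_equal(f2, f1 * 3.7, tolerance = 1e-10)
})

test_that("windowed band power matches analytic and spectral oracles", {
  rec <- sinusoid_recording(10, 2, 12)
  bp <- band_power(rec, "alpha")
  expect_true(all(abs(bp$power_uv2 - 2.0) < 0.05))

  zero <- eeg_recording(matrix(0, 1280, 14))
  bz <- band_power(zero, "alpha")
  expect_true(all(bz$power_uv2 == 0))

  # white noise: band power ratio ~ bandwidth ratio 4/16
  set.seed(42)
  wn <- eeg_recording(matrix(rnorm(60 * 128 * 14), ncol = 14))
  pa <- mean(band_power(wn, "alpha")$power_uv2)
  pb <- mean(band_power(wn, "beta")$power_uv2)
  expect_lt(abs(pa / pb - 4 / 16) / (4 / 16), 0.20)
})

test_that("time-domain band power agrees with periodogram integration", {
  set.seed(7)
  sched <- short_schedule(seed = 7)
  rec <- generate_recording(head(sched, 2), noise = noise_spec(3), seed = 7)
  fs <- eeg_srate(rec)
  for (band in c("alpha", "beta")) {
    edges <- band_edges(band)
    bp <- band_power(rec, band)
    td <- mean(dplyr::filter(bp, channel == "F3")$power_uv2)
    x <- as.data.frame(rec)$F3
    x <- x[(fs + 1):(length(x) - fs)]
    sp <- periodogram_band_power(x, fs, edges[1], edges[2])
    expect_lt(abs(td - sp) / sp, 0.10, label = paste(band, "Parseval check"))
  }
})

test_that("window grid drops filter warm-up edges and short recordings", {
  rec <- sinusoid_recording(10, 1, 10)
  bp <- band_power(rec, "alpha", window_s = 1, hop_s = 0.25)
  expect_gte(min(bp$window_center_s) - 0.5, 1) # window start after 1 s
  expect_lte(max(bp$window_center_s) + 0.5, 9) # window end before last 1 s
  centers <- sort(unique(bp$window_center_s))
  expect_equal(unique(round(diff(centers), 10)), 0.25)

  tiny <- sinusoid_recording(10, 1, 2)
  expect_warning(b2 <- band_power(tiny, "alpha"), "shorter")
  expect_equal(nrow(b2), 0)
  expect_error(band_power(rec, "alpha", window_s = 0.1), "cycles")
})

test_that("artifact rejection is silent on clean data and off with infinite thresholds", {
  sched <- short_schedule(seed = 5)
  rec <- generate_recording(head(sched, 3), noise = noise_spec(5), seed = 5)
  both <- bind_band_power(band_power(rec, "alpha"), band_power(rec, "beta"))
  expect_equal(nrow(reject_artifact_windows(rec, both)), 0)
  dirty <- inject_artifacts(rec, 6, 400, seed = 2)
  both_d <- bind_band_power(band_power(dirty, "alpha"), band_power(dirty, "beta"))
  expect_equal(nrow(reject_artifact_windows(dirty, both_d, Inf, Inf)), 0)
  expect_gt(nrow(reject_artifact_windows(dirty, both_d)), 0)
})
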