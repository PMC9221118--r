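test_that("a pure sinusoid's windowed power matches the analytic A^2/2 and a periodogram", {
  rec <- sinusoid_recording(10, amplitude_uv = 2, duration_s = 10)
  bp <- band_power(rec, "alpha")
  af3 <- dplyr::filter(bp, channel == "AF3")
  expect_true(all(abs(af3$power_uv2 - 2.0) < 0.02))
  # independent spectral oracle on the raw signal
  x <- as.data.frame(rec)$AF3
  p_spec <- periodogram_band_power(x, 128, 8, 12)
  expect_lt(abs(p_spec - 2.0) / 2.0, 0.01)
})

test_that("noiseless planted targets are recovered through the feature chain", {
  truth <- affect_ground_truth(happy = c(2.0, 1.0))
  sched <- short_schedule(seed = 4)
  happy_events <- dplyr::filter(sched, emotion == "happy")
  rec <- generate_recording(sched, truth = truth,
                            noise = noise_spec(background_uv = 0), seed = 4)
  af <- compute_affect(band_power(rec, "alpha"), band_power(rec, "beta"))
  feats <- epoch_affect(af, sched)
  happy <- dplyr::filter(feats, emotion == "happy")
  expect_lt(abs(mean(happy$arousal) - 2.0) / 2.0, 0.05)
  expect_lt(abs(mean(happy$valence) - 1.0), 0.05)
})

test_that("generation is deterministic in the seed", {
  sched <- short_schedule(seed = 2)
  r1 <- generate_recording(sched, seed = 42)
  r2 <- generate_recording(sched, seed = 42)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- generate_recording(sched, seed = 43)
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("an empty schedule yields background only and zero epochs", {
  empty <- eegaffect:::new_stimulus_schedule(
    build_schedule("EG01", "EG", 1, seed = 1)[0, ], transition_s = 5
  )
  rec <- generate_recording(empty, noise = noise_spec(background_uv = 5),
                            seed = 1, tail_s = 10)
  expect_equal(eeg_duration(rec), 10)
  af <- compute_affect(band_power(rec, "alpha"), band_power(rec, "beta"))
  feats <- epoch_affect(af, empty)
  expect_equal(nrow(feats), 0)
})

test_that("oscillator energy stays inside the 8-28 Hz band", {
  sched <- short_schedule(seed = 6)
  rec <- generate_recording(sched, noise = noise_spec(background_uv = 0), seed = 6)
  fs <- eeg_srate(rec)
  x <- as.data.frame(rec)$F4
  ev <- sched[1, ]
  idx <- (floor(ev$onset_s * fs) + 1):floor((ev$onset_s + ev$duration_s) * fs)
  seg <- x[idx]
  inband <- periodogram_band_power(seg, fs, 8, 28)
  total <- mean(seg^2)
  expect_lt((total - inband) / inband, 0.05)
})

test_that("invalid generator inputs are rejected", {
  sched <- short_schedule(seed = 1)
  bad <- sched
  bad$onset_s[2] <- bad$onset_s[1] + 1 # overlaps event 1
  bad <- bad[order(bad$onset_s), ]
  expect_error(
    generate_recording(eegaffect:::new_stimulus_schedule(bad, 5), seed = 1),
    "overlap"
  )
  expect_error(affect_ground_truth(sad = c(-1, 0)), "positive")
  expect_error(
    generate_recording(sched, noise = noise_spec(alpha_total_uv2 = 0.5), seed = 1),
    "alpha_total_uv2"
  )
})

test_that("artifact injection is inert at rate zero and detectable at high amplitude", {
  sched <- short_schedule(seed = 3)
  rec <- generate_recording(head(sched, 4), noise = noise_spec(background_uv = 5),
                            seed = 3)
  same <- inject_artifacts(rec, rate_per_min = 0, amplitude_uv = 300, seed = 1)
  expect_identical(eegaffect:::eeg_matrix(same), eegaffect:::eeg_matrix(rec))
  expect_equal(nrow(attr(same, "artifact_intervals")), 0)

  dirty <- inject_artifacts(rec, rate_per_min = 6, amplitude_uv = 300, seed = 9)
  ivals <- attr(dirty, "artifact_intervals")
  expect_gt(nrow(ivals), 0)
  both <- bind_band_power(band_power(dirty, "alpha"), band_power(dirty, "beta"))
  mask <- reject_artifact_windows(dirty, both, abs_uv = 100, z_thresh = 5)
  w <- attr(both, "window_s")
  for (k in seq_len(nrow(ivals))) {
    overlaps <- any(
      mask$window_center_s + w / 2 > ivals$onset_s[k] &
        mask$window_center_s - w / 2 < ivals$end_s[k]
    )
    expect_true(overlaps, label = sprintf("interval %d flagged", k))
  }
  expect_warning(
    inject_artifacts(rec, rate_per_min = 1, amplitude_uv = 50, seed = 1),
    "not guaranteed"
  )
  expect_error(inject_artifacts(rec, rate_per_min = -1), "non-negative")
})

test_that("full-pipeline recovery holds within 10% under low background noise", {
  truth <- affect_ground_truth()
  for (seed in 1:5) {
    feats <- pipeline_features(seed = seed, background_uv = 0.1)
    means <- feats |>
      dplyr::group_by(emotion) |>
      dplyr::summarise(ar = mean(arousal), va = mean(valence)) |>
      dplyr::inner_join(truth, by = "emotion")
    expect_true(
      all(abs(means$ar - means$target_arousal) / means$target_arousal < 0.10),
      label = sprintf("arousal recovery, seed %d", seed)
    )
    expect_true(
      all(abs(means$va - means$target_valence) /
            abs(means$target_valence) < 0.10),
      label = sprintf("valence recovery, seed %d", seed)
    )
  }
})
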