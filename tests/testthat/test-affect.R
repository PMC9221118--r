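test_that("arousal and valence follow the frontal band-power formulas", {
  sym <- manual_series(
    alpha_values = c(AF3 = 1, AF4 = 1, F3 = 1, F4 = 1),
    beta_values = c(AF3 = 1, AF4 = 1, F3 = 1, F4 = 1)
  )
  af <- compute_affect(sym)
  expect_true(all(af$arousal == 1))
  expect_true(all(af$valence == 0))

  quad <- manual_series(
    alpha_values = c(AF3 = 0.125, AF4 = 0.125, F3 = 0.125, F4 = 0.125),
    beta_values = c(AF3 = 0.5, AF4 = 0.5, F3 = 0.5, F4 = 0.5)
  )
  expect_true(all(compute_affect(quad)$arousal == 4))

  asym <- manual_series(
    alpha_values = c(AF3 = 1, AF4 = 2.0, F3 = 0.5, F4 = 2.0),
    beta_values = c(AF3 = 1, AF4 = 1, F3 = 1, F4 = 1)
  )
  expect_true(all(compute_affect(asym)$valence == 1.5))
})

test_that("arousal is scale-invariant and valence scales linearly", {
  set.seed(3)
  for (i in 1:20) {
    a <- runif(4, 0.2, 3)
    b <- runif(4, 0.2, 3)
    names(a) <- names(b) <- c("AF3", "AF4", "F3", "F4")
    c_mult <- runif(1, 0.1, 10)
    base <- compute_affect(manual_series(a, b))
    scaled <- compute_affect(manual_series(a * c_mult, b * c_mult))
    expect_equal(scaled$arousal, base$arousal, tolerance = 1e-12)
    expect_equal(scaled$valence, base$valence * c_mult, tolerance = 1e-12)
  }
})

test_that("missing channels and zero denominators are handled", {
  sym <- manual_series(
    alpha_values = c(AF3 = 1, AF4 = 1, F3 = 1, F4 = 1),
    beta_values = c(AF3 = 1, AF4 = 1, F3 = 1, F4 = 1)
  )
  broken <- dplyr::filter(sym, channel != "F4")
  broken <- eegaffect:::new_band_power_series(broken, "both", 1, 0.25)
  expect_error(compute_affect(broken), "F4")

  zero <- manual_series(
    alpha_values = c(AF3 = 0, AF4 = 0, F3 = 0, F4 = 0),
    beta_values = c(AF3 = 1, AF4 = 1, F3 = 1, F4 = 1)
  )
  expect_warning(out <- compute_affect(zero), "denominator")
  expect_equal(nrow(out), 0)
})

test_that("epoching keeps exactly the windows inside stimulus intervals", {
  sched <- short_schedule(seed = 9)
  rec <- generate_recording(sched, noise = noise_spec(0), seed = 9)
  af <- compute_affect(band_power(rec, "alpha"), band_power(rec, "beta"))
  feats <- epoch_affect(af, sched)
  # hop 0.25 s over a 10 s stimulus: 40 windows (no edge loss mid-recording)
  counts <- dplyr::count(feats, stimulus_id)
  expect_true(all(counts$n == 40))
  expect_equal(nrow(counts), 12)
  for (k in c(1, 7)) {
    ev <- sched[k, ]
    w <- dplyr::filter(feats, stimulus_id == ev$stimulus_id)
    expect_true(all(w$window_center_s >= ev$onset_s &
                      w$window_center_s < ev$onset_s + ev$duration_s))
  }
  # transition windows are excluded
  trans <- af$window_center_s[af$window_center_s < sched$onset_s[1]]
  expect_false(any(trans %in% feats$window_center_s[
    feats$stimulus_id == sched$stimulus_id[1]
  ]))
})

test_that("epoching respects masks and rejects mismatched participants", {
  sched <- short_schedule(seed = 10)
  rec <- generate_recording(sched, noise = noise_spec(0), seed = 10)
  both <- bind_band_power(band_power(rec, "alpha"), band_power(rec, "beta"))
  ev <- sched[3, ]
  grid <- sort(unique(both$window_center_s))
  mask <- tibble::tibble(
    window_center_s = grid[grid >= ev$onset_s & grid < ev$onset_s + ev$duration_s],
    reason = "amplitude"
  )
  af <- compute_affect(both, mask = eegaffect:::new_artifact_mask(mask))
  feats <- epoch_affect(af, sched)
  expect_equal(sum(feats$stimulus_id == ev$stimulus_id), 0)
  expect_equal(dplyr::n_distinct(feats$stimulus_id), 11)

  other <- build_schedule("EG02", "EG", 5, seed = 10)
  expect_error(epoch_affect(af, other), "different participants")

  empty <- eegaffect:::new_stimulus_schedule(sched[0, ], 5)
  expect_equal(nrow(epoch_affect(af, empty)), 0)
})

test_that("normalization z-scores within scope and is idempotent", {
  f1 <- pipeline_features(seed = 11, background_uv = 0.5)
  z1 <- normalize_affect(f1)
  expect_equal(mean(z1$arousal), 0, tolerance = 1e-10)
  expect_equal(stats::var(z1$arousal), 1, tolerance = 1e-10)
  expect_equal(mean(z1$valence), 0, tolerance = 1e-10)
  expect_equal(stats::var(z1$valence), 1, tolerance = 1e-10)
  z2 <- normalize_affect(z1)
  expect_equal(z2$arousal, z1$arousal, tolerance = 1e-10)

  # two participants on very different raw scales end up with identical moments
  f2 <- pipeline_features(seed = 12, background_uv = 0.5)
  f2$participant_id <- "EG02"
  f2$arousal <- f2$arousal * 10
  f2$valence <- f2$valence * 10 + 5
  both <- eegaffect:::new_epoch_feature_set(dplyr::bind_rows(f1, f2), "raw")
  z <- normalize_affect(both)
  mom <- z |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(
      ma = mean(arousal), va = stats::var(arousal),
      mv = mean(valence), vv = stats::var(valence)
    )
  expect_equal(mom$ma, c(0, 0), tolerance = 1e-10)
  expect_equal(mom$va, c(1, 1), tolerance = 1e-10)
  expect_equal(mom$mv, c(0, 0), tolerance = 1e-10)
  expect_equal(mom$vv, c(1, 1), tolerance = 1e-10)

  const <- f1
  const$arousal <- 1
  expect_error(
    normalize_affect(eegaffect:::new_epoch_feature_set(const, "raw")),
    "variance"
  )
})
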