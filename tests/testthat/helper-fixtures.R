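# Shared fixtures, all generated in code.

emos <- c("happy", "sad", "angry", "fear")

# Balanced features with no class signal: labels carry no information.
chance_features <- function(n = 1000, seed = 1) {
  withr_seed(seed)
  tibble::tibble(
    arousal = rnorm(n),
    valence = rnorm(n),
    emotion = sample(rep(emos, length.out = n))
  )
}

# Four linearly separable Gaussian clusters, one per class.
cluster_features <- function(n_per = 100, sep = 10, sd = 1, seed = 1) {
  withr_seed(seed)
  cent <- matrix(c(1, 1, -1, -1, -1, 1, 1, -1), 4, 2, byrow = TRUE) * sep / 2
  idx <- rep(1:4, each = n_per)
  tibble::tibble(
    arousal = cent[idx, 1] + rnorm(4 * n_per, 0, sd),
    valence = cent[idx, 2] + rnorm(4 * n_per, 0, sd),
    emotion = emos[idx]
  )
}

# Four classes laid out XOR-fashion: each class occupies two antipodal
# clusters, so no linear decision rule can capture a class's full region.
xor_features <- function(n_per = 40, radius = 5, sd = 0.5, seed = 1) {
  withr_seed(seed)
  ang <- c(0, 45, 90, 135) * pi / 180
  rows <- list()
  for (k in 1:4) {
    for (s in c(0, pi)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        arousal = radius * cos(ang[k] + s) + rnorm(n_per, 0, sd),
        valence = radius * sin(ang[k] + s) + rnorm(n_per, 0, sd),
        emotion = emos[k]
      )
    }
  }
  dplyr::bind_rows(rows)
}

# One-condition (follow-up assessment) schedule: 12 stimuli, ~185 s, the
# cheapest full exercise of the generator.
short_schedule <- function(seed = 1, participant = "EG01") {
  build_schedule(participant, "EG", 5, design_config(), seed = seed)
}

# Full synthesis -> filtering -> band power -> affect -> epoching chain on a
# short schedule; returns raw (un-normalized) epoch features.
pipeline_features <- function(seed = 1, background_uv = 0,
                              truth = affect_ground_truth()) {
  sched <- short_schedule(seed = seed)
  rec <- generate_recording(
    sched,
    truth = truth,
    noise = noise_spec(background_uv = background_uv),
    seed = seed
  )
  alpha <- band_power(rec, "alpha")
  beta <- band_power(rec, "beta")
  both <- bind_band_power(alpha, beta)
  mask <- reject_artifact_windows(rec, both)
  affect <- compute_affect(both, mask = mask)
  epoch_affect(affect, sched)
}

# A recording holding one pure sinusoid on every channel.
sinusoid_recording <- function(freq_hz, amplitude_uv = 1, duration_s = 10,
                               device = device_profile()) {
  n <- round(duration_s * device$sampling_rate_hz)
  t <- (seq_len(n) - 1) / device$sampling_rate_hz
  x <- amplitude_uv * sin(2 * pi * freq_hz * t)
  eeg_recording(
    matrix(rep(x, length(device$channel_names)), ncol = length(device$channel_names)),
    device = device
  )
}

# Hand-built combined band-power series on a regular grid, equal values on
# all frontal channels unless overridden.
manual_series <- function(alpha_values, beta_values, n_windows = 4) {
  grid <- seq(1.5, by = 0.25, length.out = n_windows)
  rows <- tidyr::expand_grid(
    channel = c("AF3", "AF4", "F3", "F4"),
    window_center_s = grid
  )
  rows$alpha_power_uv2 <- unname(alpha_values[rows$channel])
  rows$beta_power_uv2 <- unname(beta_values[rows$channel])
  eegaffect:::new_band_power_series(rows, "both", 1, 0.25)
}

# Periodogram band power of one channel (independent spectral oracle).
periodogram_band_power <- function(x, fs, low, high) {
  n <- length(x)
  spec <- Mod(fft(x))^2 / n^2
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq <= fs / 2
  # fold the two-sided spectrum
  p <- 2 * spec[keep]
  p[1] <- spec[1]
  sum(p[freq[keep] >= low & freq[keep] < high])
}

# local seed helper for fixtures (tests themselves use withr via testthat)
withr_seed <- function(seed) {
  set.seed(seed)
  invisible(NULL)
}
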