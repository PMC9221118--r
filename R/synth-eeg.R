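#' EEG recording container
#'
#' An `eeg_recording` is a tibble with a `time` column (seconds) and one
#' column per channel (microvolts), carrying the device profile and
#' participant metadata as attributes. Signals are stored already referenced;
#' no re-referencing is applied anywhere in the package.
#'
#' @param data Numeric matrix, samples x channels, in uV.
#' @param device A [device_profile()]; its channel names label the columns.
#' @param participant_id,group,session_index Participant metadata.
#' @param start_time_s Time of the first sample (default 0).
#' @return A tibble of class `eeg_recording`.
#' @export
eeg_recording <- function(data, device = device_profile(),
                          participant_id = "P01", group = "EG",
                          session_index = 1L, start_time_s = 0) {
  data <- as.matrix(data)
  if (ncol(data) != length(device$channel_names)) {
    abort(sprintf(
      "data has %d columns but the device montage has %d channels.",
      ncol(data), length(device$channel_names)
    ))
  }
  if (!all(is.finite(data))) {
    abort("all samples must be finite.")
  }
  colnames(data) <- device$channel_names
  out <- as_tibble(as.data.frame(data))
  out <- tibble::add_column(
    out,
    time = start_time_s + (seq_len(nrow(data)) - 1) / device$sampling_rate_hz,
    .before = 1
  )
  attr(out, "device") <- device
  attr(out, "participant_id") <- participant_id
  attr(out, "group") <- group
  attr(out, "session_index") <- as.integer(session_index)
  attr(out, "start_time_s") <- start_time_s
  class(out) <- c("eeg_recording", class(out))
  out
}

#' @export
print.eeg_recording <- function(x, ...) {
  dev <- attr(x, "device")
  cat(sprintf(
    "<eeg_recording> %s session %d (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
    attr(x, "participant_id"), attr(x, "session_index"), attr(x, "group"),
    length(dev$channel_names), nrow(x), dev$sampling_rate_hz,
    nrow(x) / dev$sampling_rate_hz
  ))
  NextMethod()
}

#' @rdname eeg_recording
#' @param rec An `eeg_recording`.
#' @export
eeg_srate <- function(rec) attr(rec, "device")$sampling_rate_hz

#' @rdname eeg_recording
#' @export
eeg_channels <- function(rec) attr(rec, "device")$channel_names

#' @rdname eeg_recording
#' @export
eeg_duration <- function(rec) nrow(rec) / eeg_srate(rec)

# samples x channels matrix view
eeg_matrix <- function(rec) {
  as.matrix(as.data.frame(rec)[, eeg_channels(rec), drop = FALSE])
}

# Replace the signal matrix, keeping all metadata.
eeg_replace_data <- function(rec, data) {
  out <- eeg_recording(
    data,
    device = attr(rec, "device"),
    participant_id = attr(rec, "participant_id"),
    group = attr(rec, "group"),
    session_index = attr(rec, "session_index"),
    start_time_s = attr(rec, "start_time_s")
  )
  attr(out, "artifact_intervals") <- attr(rec, "artifact_intervals")
  out
}

#' Noise and oscillator settings for the synthetic generator
#'
#' @param background_uv RMS amplitude (uV) of the 1/f background noise laid
#'   under every channel. 10 uV is a typical resting broadband level; set 0
#'   for a noiseless recording.
#' @param alpha_total_uv2 Total alpha power planted at F3 + F4 (uV^2). Fixes
#'   the overall oscillator scale; must exceed the largest absolute planted
#'   valence so both channel powers stay positive.
#' @param phase_drift_sd Per-sample standard deviation (radians) of the slow
#'   random phase drift given to each oscillator. Zero gives pure sinusoids.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(background_uv = 10, alpha_total_uv2 = 4,
                       phase_drift_sd = 0.02) {
  assert_scalar_number(background_uv, "background_uv")
  assert_scalar_number(alpha_total_uv2, "alpha_total_uv2", positive = TRUE)
  assert_scalar_number(phase_drift_sd, "phase_drift_sd")
  if (background_uv < 0 || phase_drift_sd < 0) {
    abort("`background_uv` and `phase_drift_sd` must be non-negative.")
  }
  structure(
    list(
      background_uv = background_uv,
      alpha_total_uv2 = alpha_total_uv2,
      phase_drift_sd = phase_drift_sd
    ),
    class = "noise_spec"
  )
}

# 1/f-spectrum noise via spectral shaping of white noise, unit RMS.
pink_noise <- function(n) {
  white <- rnorm(n)
  x <- fft(white)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) # two-sided frequency index
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- x * shape
  out <- Re(fft(x, inverse = TRUE)) / n
  out / sqrt(mean(out^2))
}

# Solve planted (arousal, valence) targets for per-channel band powers.
# Convention making the inversion unique: AF3/AF4 alpha power equals the
# mean of F3/F4 alpha power; beta power is equal across the four channels.
solve_oscillator_powers <- function(target_arousal, target_valence,
                                    alpha_total_uv2) {
  if (target_arousal <= 0) {
    abort("target arousal must be positive (it is a ratio of powers).")
  }
  if (abs(target_valence) >= alpha_total_uv2) {
    abort(sprintf(
      "|target valence| (%g) must be below `alpha_total_uv2` (%g) so both F3 and F4 alpha powers stay positive.",
      abs(target_valence), alpha_total_uv2
    ))
  }
  a_f3 <- (alpha_total_uv2 - target_valence) / 2
  a_f4 <- (alpha_total_uv2 + target_valence) / 2
  a_af <- alpha_total_uv2 / 2
  # arousal = 4*beta / (a_f3 + a_f4 + 2*a_af) = 2*beta / alpha_total
  beta <- target_arousal * alpha_total_uv2 / 2
  list(
    alpha = c(AF3 = a_af, AF4 = a_af, F3 = a_f3, F4 = a_f4),
    beta = c(AF3 = beta, AF4 = beta, F3 = beta, F4 = beta)
  )
}

#' Generate a synthetic EEG recording with planted affective structure
#'
#' Synthesizes a multichannel recording for one participant-session: 1/f
#' background noise on every channel, and, during each stimulus event,
#' narrowband alpha (10 Hz) and beta (20 Hz) oscillators on AF3, AF4, F3 and
#' F4 whose band powers encode the planted arousal and valence of the event's
#' emotion. Oscillators are amplitude-stable sinusoids with slow random phase
#' drift, so their window-averaged power equals amplitude^2 / 2 exactly.
#' Transitions between stimuli carry background only. The generation is
#' fully deterministic given `(schedule, truth, device, noise, seed)`.
#'
#' @param schedule A [build_schedule()] result (sorted, non-overlapping).
#' @param truth An [affect_ground_truth()].
#' @param device A [device_profile()] containing AF3, AF4, F3, F4.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param tail_s Extra background appended after the last event (defaults to
#'   the schedule's transition length).
#' @return An [eeg_recording()].
#' @examples
#' sched <- build_schedule("EG01", "EG", 1, seed = 1)
#' rec <- generate_recording(sched, seed = 1)
#' eeg_duration(rec)
#' @export
generate_recording <- function(schedule,
                               truth = affect_ground_truth(),
                               device = device_profile(),
                               noise = noise_spec(),
                               seed = 1,
                               tail_s = NULL) {
  validate_schedule(schedule)
  stopifnot(inherits(truth, "affect_ground_truth"), inherits(noise, "noise_spec"))
  missing_ch <- setdiff(frontal_channels, device$channel_names)
  if (length(missing_ch)) {
    abort(paste0(
      "device montage lacks required channel(s): ",
      paste(missing_ch, collapse = ", ")
    ))
  }
  if (any(truth$target_arousal <= 0)) {
    abort("all target arousal values must be positive.")
  }
  fs <- device$sampling_rate_hz
  transition <- attr(schedule, "transition_s")
  if (is.null(tail_s)) tail_s <- if (is.null(transition)) 5 else transition
  dur <- if (nrow(schedule)) max(schedule$onset_s + schedule$duration_s) + tail_s else tail_s
  n <- round(dur * fs)
  n_ch <- length(device$channel_names)

  with_seed(seed, {
    data <- matrix(0, nrow = n, ncol = n_ch,
                   dimnames = list(NULL, device$channel_names))
    if (noise$background_uv > 0) {
      for (ch in seq_len(n_ch)) {
        data[, ch] <- pink_noise(n) * noise$background_uv
      }
    }
    truth_idx <- stats::setNames(seq_len(nrow(truth)), truth$emotion)
    for (ev in seq_len(nrow(schedule))) {
      emo <- schedule$emotion[ev]
      if (!emo %in% names(truth_idx)) {
        abort(sprintf("no ground-truth targets for emotion '%s'.", emo))
      }
      row <- truth[truth_idx[[emo]], ]
      pw <- solve_oscillator_powers(
        row$target_arousal, row$target_valence, noise$alpha_total_uv2
      )
      i0 <- floor(schedule$onset_s[ev] * fs) + 1
      i1 <- min(n, floor((schedule$onset_s[ev] + schedule$duration_s[ev]) * fs))
      idx <- i0:i1
      t <- (idx - 1) / fs
      for (ch in frontal_channels) {
        for (band in c("alpha", "beta")) {
          f0 <- if (band == "alpha") 10 else 20
          amp <- sqrt(2 * pw[[band]][[ch]])
          phase <- 2 * pi * f0 * t + runif(1, 0, 2 * pi)
          if (noise$phase_drift_sd > 0) {
            phase <- phase + cumsum(rnorm(length(idx), 0, noise$phase_drift_sd))
          }
          data[idx, ch] <- data[idx, ch] + amp * cos(phase)
        }
      }
    }
    eeg_recording(
      data,
      device = device,
      participant_id = schedule$participant_id[1] %||% "P01",
      group = schedule$group[1] %||% "EG",
      session_index = schedule$session_index[1] %||% 1L
    )
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Inject transient high-amplitude artifacts
#'
#' Adds movement-like transient excursions (smooth raised-cosine bumps of
#' 0.25-1 s) at Poisson-distributed times across all channels, emulating the
#' gross artifacts an analyst would mark during visual inspection. The true
#' artifact intervals are stored in the `artifact_intervals` attribute so
#' detector performance can be assessed against ground truth.
#'
#' @param rec An [eeg_recording()].
#' @param rate_per_min Expected artifacts per minute (non-negative).
#' @param amplitude_uv Peak excursion amplitude in uV. Should exceed the
#'   absolute rejection threshold in use (default 100 uV); a warning is
#'   given otherwise, since such artifacts are not guaranteed to be flagged.
#' @param seed Integer seed.
#' @return A new `eeg_recording` with attribute `artifact_intervals`, a
#'   tibble of `(onset_s, end_s)` rows (empty when `rate_per_min = 0`).
#' @export
inject_artifacts <- function(rec, rate_per_min, amplitude_uv = 300, seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_number(rate_per_min, "rate_per_min")
  if (rate_per_min < 0) {
    abort("`rate_per_min` must be non-negative.")
  }
  assert_scalar_number(amplitude_uv, "amplitude_uv", positive = TRUE)
  if (amplitude_uv < 100) {
    warn("`amplitude_uv` is below the default 100 uV rejection threshold; injected artifacts are not guaranteed to be flagged.")
  }
  intervals <- tibble(onset_s = numeric(), end_s = numeric())
  if (rate_per_min == 0) {
    attr(rec, "artifact_intervals") <- intervals
    return(rec)
  }
  fs <- eeg_srate(rec)
  dur <- eeg_duration(rec)
  data <- eeg_matrix(rec)
  with_seed(seed, {
    n_art <- rpois(1, rate_per_min * dur / 60)
    if (n_art > 0) {
      onsets <- sort(runif(n_art, 0, max(dur - 1, 0)))
      lengths_s <- runif(n_art, 0.25, 1)
      for (k in seq_len(n_art)) {
        i0 <- floor(onsets[k] * fs) + 1
        i1 <- min(nrow(data), i0 + round(lengths_s[k] * fs) - 1)
        m <- i1 - i0 + 1
        bump <- amplitude_uv * 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
        sign <- sample(c(-1, 1), 1)
        data[i0:i1, ] <- data[i0:i1, ] + sign * bump
      }
      intervals <- tibble(
        onset_s = onsets,
        end_s = pmin(onsets + lengths_s, dur)
      )
    }
  })
  out <- eeg_replace_data(rec, data)
  attr(out, "artifact_intervals") <- intervals
  out
}
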