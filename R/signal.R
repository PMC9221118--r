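#' EEG frequency bands used by the affect estimators
#'
#' Alpha is 8-12 Hz and beta is 12-28 Hz, the bands whose power ratio and
#' asymmetry define the arousal and valence estimators.
#'
#' @param band `"alpha"` or `"beta"`.
#' @return Length-2 numeric vector `c(low_hz, high_hz)`.
#' @export
band_edges <- function(band = c("alpha", "beta")) {
  band <- match.arg(band)
  if (band == "alpha") c(8, 12) else c(12, 28)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (zero phase, so stimulus-locked epochs keep their alignment) to every
#' channel of a recording.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order Filter order (default 4).
#' @return A filtered `eeg_recording` of the same shape and units.
#' @examples
#' sched <- build_schedule("EG01", "EG", 1, seed = 1)
#' rec <- generate_recording(head(sched, 2), seed = 1)
#' alpha_rec <- bandpass(rec, 8, 12)
#' @export
bandpass <- function(rec, low_hz, high_hz, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- eeg_srate(rec)
  assert_scalar_number(low_hz, "low_hz", positive = TRUE)
  assert_scalar_number(high_hz, "high_hz", positive = TRUE)
  if (low_hz >= high_hz) {
    abort("`low_hz` must be below `high_hz`.")
  }
  if (high_hz >= fs / 2) {
    abort(sprintf(
      "`high_hz` (%g Hz) must be below the Nyquist frequency (%g Hz).",
      high_hz, fs / 2
    ))
  }
  filt <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  data <- eeg_matrix(rec)
  for (ch in seq_len(ncol(data))) {
    data[, ch] <- signal::filtfilt(filt, data[, ch])
  }
  eeg_replace_data(rec, data)
}

# Sliding-window grid over a recording; centers in seconds.
window_grid <- function(duration_s, window_s, hop_s, edge_s) {
  first <- max(window_s / 2, edge_s + window_s / 2)
  last <- duration_s - max(window_s / 2, edge_s + window_s / 2)
  if (last < first - 1e-9) {
    return(numeric(0))
  }
  seq(first, last + 1e-9, by = hop_s)
}

#' Windowed band power of a recording
#'
#' Band-pass filters the recording ([bandpass()]) and computes, per channel
#' and sliding window, the mean of squared samples (uV^2) over
#' `[center - window_s/2, center + window_s/2)`. The window grid steps by
#' `hop_s`; windows overlapping the filter warm-up (`edge_s` at each end of
#' the recording) are dropped.
#'
#' @param rec An [eeg_recording()].
#' @param band `"alpha"` (8-12 Hz) or `"beta"` (12-28 Hz).
#' @param window_s Window length in seconds (default 1, >= 8 alpha cycles).
#' @param hop_s Hop between window centers in seconds (default 0.25).
#' @param edge_s Guard interval dropped at each end (default 1 s).
#' @param order Butterworth filter order (default 4).
#' @return A tibble of class `band_power_series` with columns `channel`,
#'   `window_center_s`, `power_uv2`, and attributes `band`, `window_s`,
#'   `hop_s`. Empty (with a warning) if the recording is shorter than one
#'   window plus guards.
#' @examples
#' sched <- build_schedule("EG01", "EG", 1, seed = 1)
#' rec <- generate_recording(head(sched, 1), noise = noise_spec(0), seed = 1)
#' bp <- band_power(rec, "alpha")
#' head(bp)
#' @export
band_power <- function(rec, band = c("alpha", "beta"), window_s = 1,
                       hop_s = 0.25, edge_s = 1, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  band <- match.arg(band)
  edges <- band_edges(band)
  assert_scalar_number(window_s, "window_s", positive = TRUE)
  assert_scalar_number(hop_s, "hop_s", positive = TRUE)
  if (window_s < 2 / edges[1]) {
    abort(sprintf(
      "`window_s` must cover at least 2 cycles of the band's low edge (>= %.3f s).",
      2 / edges[1]
    ))
  }
  fs <- eeg_srate(rec)
  centers <- window_grid(eeg_duration(rec), window_s, hop_s, edge_s)
  empty <- tibble(
    channel = character(), window_center_s = numeric(), power_uv2 = numeric()
  )
  if (length(centers) == 0) {
    warn("recording is shorter than one analysis window; returning an empty series.")
    return(new_band_power_series(
      empty, band, window_s, hop_s,
      attr(rec, "participant_id"), attr(rec, "session_index")
    ))
  }
  filtered <- bandpass(rec, edges[1], edges[2], order = order)
  data <- eeg_matrix(filtered)
  w_len <- round(window_s * fs)
  starts <- floor((centers - window_s / 2) * fs) + 1
  out <- purrr::map(eeg_channels(rec), function(ch) {
    csum <- c(0, cumsum(data[, ch]^2))
    p <- (csum[starts + w_len] - csum[starts]) / w_len
    tibble(channel = ch, window_center_s = centers, power_uv2 = p)
  })
  new_band_power_series(
    bind_rows(out), band, window_s, hop_s,
    attr(rec, "participant_id"), attr(rec, "session_index")
  )
}

new_band_power_series <- function(x, band, window_s, hop_s,
                                  participant_id = NULL, session_index = NULL) {
  attr(x, "band") <- band
  attr(x, "window_s") <- window_s
  attr(x, "hop_s") <- hop_s
  attr(x, "participant_id") <- participant_id
  attr(x, "session_index") <- session_index
  class(x) <- c("band_power_series", class(x))
  x
}

#' Combine alpha and beta band-power series on a shared window grid
#'
#' @param alpha,beta Single-band `band_power_series` from [band_power()],
#'   computed on the same recording with identical windowing.
#' @return A tibble of class `band_power_series` with columns `channel`,
#'   `window_center_s`, `alpha_power_uv2`, `beta_power_uv2`.
#' @export
bind_band_power <- function(alpha, beta) {
  stopifnot(inherits(alpha, "band_power_series"), inherits(beta, "band_power_series"))
  if (!identical(attr(alpha, "band"), "alpha") || !identical(attr(beta, "band"), "beta")) {
    abort("`alpha` and `beta` must be series of those respective bands.")
  }
  a <- as_tibble(alpha) %>% rename(alpha_power_uv2 = "power_uv2")
  b <- as_tibble(beta) %>% rename(beta_power_uv2 = "power_uv2")
  merged <- inner_join(a, b, by = c("channel", "window_center_s"))
  if (nrow(merged) != nrow(a) || nrow(merged) != nrow(b)) {
    abort("alpha and beta series are not on the same window grid.")
  }
  new_band_power_series(
    merged,
    band = "both", attr(alpha, "window_s"), attr(alpha, "hop_s"),
    attr(alpha, "participant_id"), attr(alpha, "session_index")
  )
}

#' Flag artifact-contaminated analysis windows
#'
#' Automated surrogate for visual artifact inspection. A window is rejected
#' when (a) any of AF3, AF4, F3, F4 exceeds `abs_uv` in absolute raw
#' amplitude within the window, or (b) the window's total frontal band power
#' (alpha + beta summed over the four channels) has a z-score above
#' `z_thresh` across the recording. Reasons are reported per window.
#'
#' @param rec The raw (unfiltered) [eeg_recording()].
#' @param series A combined band-power series from [bind_band_power()].
#' @param abs_uv Absolute amplitude threshold in uV (default 100).
#' @param z_thresh Total-power z-score threshold (default 5).
#' @return A tibble of class `artifact_mask` with columns `window_center_s`,
#'   `reason` (`"amplitude"`, `"power_outlier"` or both, `;`-separated).
#'   Empty when nothing is rejected.
#' @export
reject_artifact_windows <- function(rec, series, abs_uv = 100, z_thresh = 5) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(series, "band_power_series"))
  # Inf disables a threshold, so only NA/NaN and non-positive values are invalid.
  for (nm in c("abs_uv", "z_thresh")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number (Inf allowed).", nm))
    }
  }
  if (!all(c("alpha_power_uv2", "beta_power_uv2") %in% names(series))) {
    abort("`series` must hold both bands; see bind_band_power().")
  }
  missing_ch <- setdiff(frontal_channels, unique(series$channel))
  if (length(missing_ch)) {
    abort(paste0(
      "`series` lacks frontal channel(s): ", paste(missing_ch, collapse = ", ")
    ))
  }
  centers <- sort(unique(series$window_center_s))
  mask <- tibble(window_center_s = numeric(), reason = character())
  if (length(centers) == 0) {
    return(new_artifact_mask(mask))
  }
  fs <- eeg_srate(rec)
  window_s <- attr(series, "window_s")
  data <- eeg_matrix(rec)[, frontal_channels, drop = FALSE]
  w_len <- round(window_s * fs)
  starts <- floor((centers - window_s / 2) * fs) + 1
  peak <- vapply(seq_along(centers), function(i) {
    idx <- starts[i]:min(nrow(data), starts[i] + w_len - 1)
    max(abs(data[idx, ]))
  }, numeric(1))

  total <- series %>%
    filter(.data$channel %in% frontal_channels) %>%
    group_by(.data$window_center_s) %>%
    summarise(
      total_power = sum(.data$alpha_power_uv2 + .data$beta_power_uv2),
      .groups = "drop"
    ) %>%
    arrange(.data$window_center_s)
  z <- if (nrow(total) > 1 && sd(total$total_power) > 0) {
    (total$total_power - mean(total$total_power)) / sd(total$total_power)
  } else {
    rep(0, nrow(total))
  }

  amp_bad <- is.finite(abs_uv) & peak > abs_uv
  pow_bad <- is.finite(z_thresh) & z > z_thresh
  bad <- amp_bad | pow_bad
  if (any(bad)) {
    reason <- character(sum(bad))
    reason <- paste0(
      ifelse(amp_bad[bad], "amplitude", ""),
      ifelse(amp_bad[bad] & pow_bad[bad], ";", ""),
      ifelse(pow_bad[bad], "power_outlier", "")
    )
    mask <- tibble(window_center_s = centers[bad], reason = reason)
  }
  new_artifact_mask(mask)
}

new_artifact_mask <- function(x) {
  class(x) <- c("artifact_mask", class(x))
  x
}
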