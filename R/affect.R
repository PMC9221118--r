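#' Instantaneous arousal and valence from frontal band power
#'
#' Per analysis window, arousal is the beta/alpha band-power ratio summed
#' over the four prefrontal channels,
#' `(bF3 + bF4 + bAF3 + bAF4) / (aF3 + aF4 + aAF3 + aAF4)`, and valence is
#' the frontal alpha asymmetry `aF4 - aF3` (uV^2); greater right-hemisphere
#' alpha reads as positive valence. Windows flagged by the artifact mask are
#' omitted; windows with a zero alpha denominator are dropped with a warning
#' (the ratio would be uninterpretable).
#'
#' @param alpha,beta Single-band [band_power()] series on the same grid, or
#'   a combined series from [bind_band_power()] as `alpha` with `beta` absent.
#' @param mask Optional [reject_artifact_windows()] mask.
#' @return A tibble of class `affect_series` with columns `window_center_s`,
#'   `arousal`, `valence`; attributes `participant_id`, `session_index`,
#'   `normalization = "raw"` (carried from the series when available).
#' @examples
#' sched <- build_schedule("EG01", "EG", 1, seed = 1)
#' rec <- generate_recording(head(sched, 2), noise = noise_spec(0), seed = 1)
#' af <- compute_affect(band_power(rec, "alpha"), band_power(rec, "beta"))
#' head(af)
#' @export
compute_affect <- function(alpha, beta = NULL, mask = NULL) {
  series <- if (is.null(beta)) {
    stopifnot(inherits(alpha, "band_power_series"))
    if (!all(c("alpha_power_uv2", "beta_power_uv2") %in% names(alpha))) {
      abort("single-argument form needs a combined series from bind_band_power().")
    }
    alpha
  } else {
    bind_band_power(alpha, beta)
  }
  missing_ch <- setdiff(frontal_channels, unique(series$channel))
  if (length(missing_ch)) {
    abort(paste0(
      "required channel(s) missing from band-power series: ",
      paste(missing_ch, collapse = ", ")
    ))
  }
  wide <- series %>%
    filter(.data$channel %in% frontal_channels) %>%
    tidyr::pivot_wider(
      id_cols = "window_center_s",
      names_from = "channel",
      values_from = c("alpha_power_uv2", "beta_power_uv2")
    ) %>%
    arrange(.data$window_center_s)

  if (!is.null(mask) && nrow(mask) > 0) {
    wide <- filter(wide, !.data$window_center_s %in% mask$window_center_s)
  }
  denom <- wide$alpha_power_uv2_F3 + wide$alpha_power_uv2_F4 +
    wide$alpha_power_uv2_AF3 + wide$alpha_power_uv2_AF4
  zero <- denom <= 0
  if (any(zero)) {
    warn(sprintf(
      "%d window(s) dropped: zero alpha-power denominator.", sum(zero)
    ))
    wide <- wide[!zero, , drop = FALSE]
    denom <- denom[!zero]
  }
  numer <- wide$beta_power_uv2_F3 + wide$beta_power_uv2_F4 +
    wide$beta_power_uv2_AF3 + wide$beta_power_uv2_AF4
  out <- tibble(
    window_center_s = wide$window_center_s,
    arousal = numer / denom,
    valence = wide$alpha_power_uv2_F4 - wide$alpha_power_uv2_F3
  )
  new_affect_series(
    out,
    participant_id = attr(series, "participant_id"),
    session_index = attr(series, "session_index"),
    normalization = "raw"
  )
}

new_affect_series <- function(x, participant_id = NULL, session_index = NULL,
                              normalization = "raw") {
  attr(x, "participant_id") <- participant_id
  attr(x, "session_index") <- session_index
  attr(x, "normalization") <- normalization
  class(x) <- c("affect_series", class(x))
  x
}

#' Epoch an affect series by stimulus events
#'
#' Keeps exactly the affect windows whose centers fall inside a stimulus
#' interval `[onset, onset + duration)` and labels them with the event's
#' emotion, condition and stimulus id. Transition windows (and windows
#' already removed by the artifact mask) are absent from the result. Events
#' whose windows were all masked contribute zero rows.
#'
#' @param affect An [compute_affect()] series.
#' @param schedule The [build_schedule()] of the same participant-session.
#' @return A tibble of class `epoch_feature_set`: one row per retained
#'   window with columns `participant_id`, `group`, `session_index`,
#'   `condition`, `stimulus_id`, `emotion`, `window_center_s`, `arousal`,
#'   `valence`; attribute `normalization` carried from `affect`.
#' @export
epoch_affect <- function(affect, schedule) {
  stopifnot(inherits(affect, "affect_series"))
  validate_schedule(schedule)
  aff_pid <- attr(affect, "participant_id")
  if (!is.null(aff_pid) && nrow(schedule) > 0 &&
      !is.null(schedule$participant_id) &&
      !identical(aff_pid, schedule$participant_id[1])) {
    abort(sprintf(
      "affect series (%s) and schedule (%s) refer to different participants.",
      aff_pid, schedule$participant_id[1]
    ))
  }
  empty <- tibble(
    participant_id = character(), group = character(),
    session_index = integer(), condition = character(),
    stimulus_id = character(), emotion = character(),
    window_center_s = numeric(), arousal = numeric(), valence = numeric()
  )
  if (nrow(schedule) == 0 || nrow(affect) == 0) {
    return(new_epoch_feature_set(empty, attr(affect, "normalization") %||% "raw"))
  }
  rows <- purrr::map(seq_len(nrow(schedule)), function(ev) {
    on <- schedule$onset_s[ev]
    off <- on + schedule$duration_s[ev]
    keep <- affect$window_center_s >= on & affect$window_center_s < off
    if (!any(keep)) {
      return(NULL)
    }
    tibble(
      participant_id = schedule$participant_id[ev] %||% (aff_pid %||% NA_character_),
      group = schedule$group[ev] %||% NA_character_,
      session_index = as.integer(schedule$session_index[ev] %||%
        (attr(affect, "session_index") %||% NA_integer_)),
      condition = schedule$condition[ev],
      stimulus_id = schedule$stimulus_id[ev],
      emotion = schedule$emotion[ev],
      window_center_s = affect$window_center_s[keep],
      arousal = affect$arousal[keep],
      valence = affect$valence[keep]
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- empty
  new_epoch_feature_set(out, attr(affect, "normalization") %||% "raw")
}

new_epoch_feature_set <- function(x, normalization = "raw") {
  attr(x, "normalization") <- normalization
  class(x) <- unique(c("epoch_feature_set", class(x)))
  x
}

#' Z-score epoched affect features
#'
#' Standardizes arousal and valence independently within a normalization
#' scope: `"participant_session"` (the default; removes session-to-session
#' gain and impedance drift and matches per-session comparisons) or
#' `"participant_study"` (one scale per participant across all sessions).
#'
#' @param features An [epoch_affect()] feature set.
#' @param scope Grouping within which to z-score.
#' @return The feature set with standardized `arousal` and `valence` and
#'   attribute `normalization = "zscored"`.
#' @export
normalize_affect <- function(features,
                             scope = c("participant_session", "participant_study")) {
  stopifnot(inherits(features, "epoch_feature_set"))
  scope <- match.arg(scope)
  if (nrow(features) == 0) {
    abort("cannot normalize an empty feature set.")
  }
  keys <- if (scope == "participant_session") {
    c("participant_id", "session_index")
  } else {
    "participant_id"
  }
  norm <- attr(features, "normalization")
  grouped <- features %>%
    group_by(dplyr::across(dplyr::all_of(keys)))
  sizes <- dplyr::group_size(grouped)
  if (any(sizes < 2)) {
    abort("every normalization group needs at least 2 rows.")
  }
  sds <- grouped %>%
    summarise(
      sd_a = sd(.data$arousal), sd_v = sd(.data$valence), .groups = "drop"
    )
  if (any(sds$sd_a == 0) || any(sds$sd_v == 0)) {
    abort("zero variance within a normalization group; cannot z-score.")
  }
  out <- grouped %>%
    mutate(
      arousal = (.data$arousal - mean(.data$arousal)) / sd(.data$arousal),
      valence = (.data$valence - mean(.data$valence)) / sd(.data$valence)
    ) %>%
    ungroup()
  new_epoch_feature_set(out, normalization = "zscored")
}
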