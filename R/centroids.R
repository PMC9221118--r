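#' Per-emotion arousal-valence centroids
#'
#' For each emotion, averages the (valence, arousal) coordinates of every
#' retained feature window of the requested condition and session across
#' participants, then rescales the four centroids jointly by their maximum
#' absolute coordinate so they fit the unit square of the Thayer plane while
#' preserving their geometry and axis rank order.
#'
#' @param features A z-scored [epoch_feature_set][normalize_affect()].
#' @param condition Condition to select (default `"NM1"`).
#' @param session_tag `"session1"` (first session) or `"post_session4"` (the
#'   follow-up assessment one week after the last session).
#' @param session_map Named integer vector mapping tags to session indices.
#' @param group Restrict to one group (default `"EG"`; `NULL` pools both).
#' @return A tibble of class `centroid_set` with columns `emotion`,
#'   `valence_norm`, `arousal_norm`, `n_windows`, and attributes `condition`
#'   and `session_tag`. Coordinates lie in `[-1, 1]`.
#' @export
compute_centroids <- function(features, condition = "NM1",
                              session_tag = c("session1", "post_session4"),
                              session_map = c(session1 = 1L, post_session4 = 5L),
                              group = "EG") {
  stopifnot(inherits(features, "epoch_feature_set"))
  session_tag <- match.arg(session_tag)
  if (!identical(attr(features, "normalization"), "zscored")) {
    abort("features must be z-scored first; see normalize_affect().")
  }
  if (!condition %in% unique(features$condition)) {
    abort(sprintf("condition '%s' is absent from the feature set.", condition))
  }
  sel <- features %>%
    filter(
      .data$condition == !!condition,
      .data$session_index == session_map[[session_tag]]
    )
  if (!is.null(group) && "group" %in% names(sel)) {
    sel <- filter(sel, .data$group == !!group)
  }
  counts <- sel %>% count(.data$emotion)
  missing <- setdiff(emotion_levels, counts$emotion)
  if (length(missing)) {
    abort(sprintf(
      "emotion '%s' has zero feature windows in %s/%s.",
      missing[1], condition, session_tag
    ))
  }
  cen <- sel %>%
    group_by(.data$emotion) %>%
    summarise(
      valence_norm = mean(.data$valence),
      arousal_norm = mean(.data$arousal),
      n_windows = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(emotion = factor(.data$emotion, levels = emotion_levels)) %>%
    arrange(.data$emotion) %>%
    mutate(emotion = as.character(.data$emotion))
  m <- max(abs(c(cen$valence_norm, cen$arousal_norm)))
  if (m > 0) {
    cen <- mutate(
      cen,
      valence_norm = .data$valence_norm / m,
      arousal_norm = .data$arousal_norm / m
    )
  }
  attr(cen, "condition") <- condition
  attr(cen, "session_tag") <- session_tag
  class(cen) <- c("centroid_set", class(cen))
  cen
}

#' Agreement of centroids with an expected quadrant layout
#'
#' Checks, per emotion, whether the centroid's (valence, arousal) signs
#' match the expected Thayer-plane quadrant. A centroid lying exactly on an
#' axis is flagged `indeterminate` and counted as neither match nor
#' mismatch.
#'
#' @param centroids A [compute_centroids()] result.
#' @param expected An [emotion_layout()]-style tibble with `emotion`,
#'   `valence_sign`, `arousal_sign`.
#' @return A tibble of class `agreement_report` with per-emotion `status`
#'   (`"match"`, `"mismatch"`, `"indeterminate"`) and attributes `n_match`,
#'   `n_indeterminate`.
#' @examples
#' feats <- tibble::tibble(
#'   participant_id = "EG01", group = "EG", session_index = 1L,
#'   condition = "NM1", stimulus_id = rep(paste0("s", 1:8), each = 10),
#'   emotion = rep(c("happy", "sad", "angry", "fear"), each = 20),
#'   window_center_s = rep(1:20, 4),
#'   arousal = rep(c(2, 0.5, 2.5, 2.2), each = 20) + rnorm(80, 0, 0.01),
#'   valence = rep(c(1, -0.5, -1, -0.8), each = 20) + rnorm(80, 0, 0.01)
#' )
#' feats <- new_epoch_feature_set(feats)
#' cen <- compute_centroids(normalize_affect(feats), session_tag = "session1")
#' quadrant_agreement(cen)
#' @export
quadrant_agreement <- function(centroids, expected = emotion_layout()) {
  stopifnot(inherits(centroids, "centroid_set"))
  req <- c("emotion", "valence_sign", "arousal_sign")
  if (!all(req %in% names(expected))) {
    abort("`expected` must have columns emotion, valence_sign, arousal_sign.")
  }
  out <- centroids %>%
    as_tibble() %>%
    inner_join(expected, by = "emotion") %>%
    mutate(
      on_axis = .data$valence_norm == 0 | .data$arousal_norm == 0,
      match = sign(.data$valence_norm) == .data$valence_sign &
        sign(.data$arousal_norm) == .data$arousal_sign,
      status = dplyr::case_when(
        .data$on_axis ~ "indeterminate",
        .data$match ~ "match",
        TRUE ~ "mismatch"
      )
    ) %>%
    select("emotion", "valence_norm", "arousal_norm", "valence_sign",
           "arousal_sign", "status")
  attr(out, "n_match") <- sum(out$status == "match")
  attr(out, "n_indeterminate") <- sum(out$status == "indeterminate")
  class(out) <- c("agreement_report", class(out))
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> %d/4 centroids in their expected quadrant (%d indeterminate)\n",
    attr(x, "n_match"), attr(x, "n_indeterminate")
  ))
  NextMethod()
}

#' Plot a centroid set on the Thayer plane
#'
#' Valence on the x-axis, arousal on the y-axis, one labelled point per
#' emotion, axes crossing at the origin.
#'
#' @param object A [compute_centroids()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot centroid_set
#' @export
autoplot.centroid_set <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$valence_norm, y = .data$arousal_norm)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$emotion), size = 3) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$emotion),
      nudge_y = 0.07, show.legend = FALSE
    ) +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(
      x = "valence (normalized)", y = "arousal (normalized)",
      title = sprintf(
        "Arousal-valence centroids (%s, %s)",
        attr(object, "condition"), attr(object, "session_tag")
      )
    ) +
    ggplot2::theme_minimal()
}
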