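#' Tidy a cross-validation result
#'
#' @param x A `cv_result` from [train_eval_ann()] or
#'   [train_eval_linear_svm()].
#' @param ... Unused.
#' @return One row per evaluated fold: `repeat_index`, `fold`, `accuracy`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  tibble(
    repeat_index = rep(seq_len(x$repeats), each = x$folds),
    fold = rep(seq_len(x$folds), x$repeats),
    accuracy = x$fold_accuracy
  )
}

#' @rdname tidy.cv_result
#' @return `glance()` returns a one-row summary.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    classifier = x$classifier,
    folds = x$folds,
    repeats = x$repeats,
    n_instances = x$n_instances,
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = sd(x$fold_accuracy),
    seed = x$seed
  )
}

#' Tidy a statistical test report
#'
#' @param x An `affect_test_report` (e.g. from [wilcoxon_exact()],
#'   [normality_gate()]).
#' @param ... Unused.
#' @return A one-row tibble with the test name, statistic, p-value, n,
#'   decision and note.
#' @method tidy affect_test_report
#' @export
tidy.affect_test_report <- function(x, ...) {
  tibble(
    test = x$test_name,
    statistic = x$statistic,
    p_value = x$p_value,
    n = x$n,
    alpha = x$alpha,
    significant = x$significant,
    route = x$route %||% NA_character_,
    note = x$note
  )
}

#' Tidy a model comparison report
#'
#' @param x A `comparison_report` from [compare_models()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) {
  tibble(
    classifier_a = x$classifiers[1],
    classifier_b = x$classifiers[2],
    mean_diff = x$mean_diff,
    p_value = x$p_value,
    alpha = x$alpha,
    significant = x$significant,
    n_folds = x$n_folds,
    method = x$method
  )
}

#' Plot an affect series
#'
#' Arousal and valence traces over time, faceted, with stimulus intervals
#' shaded when a schedule is supplied.
#'
#' @param object An [compute_affect()] series.
#' @param schedule Optional [build_schedule()] to shade stimulus intervals.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot affect_series
#' @export
autoplot.affect_series <- function(object, schedule = NULL, ...) {
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(c("arousal", "valence"),
                        names_to = "feature", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$window_center_s, y = .data$value))
  if (!is.null(schedule) && nrow(schedule) > 0) {
    shade <- tibble(
      xmin = schedule$onset_s,
      xmax = schedule$onset_s + schedule$duration_s,
      emotion = schedule$emotion
    )
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$emotion),
      alpha = 0.2, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
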