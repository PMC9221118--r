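#' Per-cell verbal-response accuracy
#'
#' Tallies correct responses per participant-session-condition cell.
#'
#' @param responses A [simulate_verbal_responses()]-style tibble (columns
#'   `participant_id`, `group`, `session_index`, `condition`, `stimulus_id`,
#'   `correct`).
#' @return A tibble with one row per cell: `participant_id`, `group`,
#'   `session_index`, `condition`, `n_correct`, `n_total`, `accuracy`.
#'   Empty input gives an empty table with a warning.
#' @export
accuracy_table <- function(responses) {
  req <- c("participant_id", "group", "session_index", "condition",
           "stimulus_id", "correct")
  missing <- setdiff(req, names(responses))
  if (length(missing)) {
    abort(paste0("responses lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(responses) == 0) {
    warn("empty response table.")
    return(tibble(
      participant_id = character(), group = character(),
      session_index = integer(), condition = character(),
      n_correct = integer(), n_total = integer(), accuracy = numeric()
    ))
  }
  dup <- responses %>%
    count(.data$participant_id, .data$session_index, .data$condition,
          .data$stimulus_id) %>%
    filter(n > 1)
  if (nrow(dup)) {
    abort(sprintf(
      "duplicate response row(s), e.g. %s session %s %s stimulus %s.",
      dup$participant_id[1], dup$session_index[1], dup$condition[1],
      dup$stimulus_id[1]
    ))
  }
  responses %>%
    group_by(.data$participant_id, .data$group, .data$session_index,
             .data$condition) %>%
    summarise(
      n_correct = sum(.data$correct),
      n_total = dplyr::n(),
      accuracy = mean(.data$correct),
      .groups = "drop"
    )
}

# ---- exact Wilcoxon matched-pairs signed-rank ----------------------------

# Exact null distribution of the positive-rank sum W+ conditional on the
# observed |difference| ranks (average ranks for ties, zeros dropped by
# Wilcoxon's rule). Doubling the ranks keeps tied average ranks integral,
# so the distribution is a simple polynomial convolution; this stays exact
# in the presence of ties, where the unconditional distribution does not
# apply.
signed_rank_distribution <- function(ranks2) {
  total <- sum(ranks2)
  coef <- c(1, rep(0, total))
  for (r in ranks2) {
    shifted <- c(rep(0, r), coef[seq_len(total + 1 - r)])
    coef <- coef + shifted
  }
  coef / 2^length(ranks2)
}

#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test on paired differences with Wilcoxon's
#' zero-handling rule (zero differences dropped, effective n reported) and
#' an exact conditional null distribution that remains valid under tied
#' ranks. All differences zero gives p = 1 with a note.
#'
#' @param d Numeric vector of paired differences.
#' @param alpha Significance level recorded in the report (default 0.05).
#' @return An `affect_test_report` with the rank-sum statistic `V` (sum of
#'   positive ranks), the exact two-sided p-value, `n` (effective, zeros
#'   dropped), and the decision at `alpha`.
#' @examples
#' wilcoxon_exact(c(2, 1, 3, 1, 2, 4, 1, 2))
#' @export
wilcoxon_exact <- function(d, alpha = 0.05) {
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new_test_report(
      "Wilcoxon matched-pairs signed-rank (exact)", statistic = 0,
      p_value = 1, n = 0, alpha = alpha,
      note = "all paired differences are zero"
    ))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  ranks2 <- as.integer(round(2 * r))
  dist <- signed_rank_distribution(ranks2)
  w2 <- as.integer(round(2 * w_plus))
  p_le <- sum(dist[seq_len(w2 + 1)])
  p_ge <- sum(dist[(w2 + 1):length(dist)])
  p <- min(1, 2 * min(p_le, p_ge))
  note <- if (n_zero > 0) {
    sprintf("%d zero difference(s) dropped (effective n = %d)", n_zero, n)
  } else {
    NA_character_
  }
  new_test_report(
    "Wilcoxon matched-pairs signed-rank (exact)",
    statistic = w_plus, p_value = p, n = n, alpha = alpha, note = note
  )
}

new_test_report <- function(test_name, statistic, p_value, n, alpha,
                            note = NA_character_, extra = list()) {
  structure(
    c(
      list(
        test_name = test_name, statistic = statistic, p_value = p_value,
        n = n, alpha = alpha, significant = p_value <= alpha, note = note
      ),
      extra
    ),
    class = "affect_test_report"
  )
}

#' @export
print.affect_test_report <- function(x, ...) {
  cat(sprintf(
    "<test_report> %s: statistic = %.4g, p = %.4g, n = %d%s\n",
    x$test_name, x$statistic, x$p_value, x$n,
    if (!is.na(x$note)) paste0(" (", x$note, ")") else ""
  ))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Tests paired differences for normality and routes the downstream
#' comparison: `p >= 0.05` keeps the parametric branch (paired t), smaller
#' p routes to the non-parametric signed-rank branch.
#'
#' @param x Numeric vector (3 to 50 values, non-constant).
#' @param alpha Routing threshold (default 0.05).
#' @return An `affect_test_report` with `route` (`"parametric"` or
#'   `"nonparametric"`) and the W statistic.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 50) {
    abort("`x` must hold between 3 and 50 values.")
  }
  if (sd(x) == 0) {
    abort("`x` is constant; the Shapiro-Wilk W statistic is undefined.")
  }
  sw <- shapiro.test(x)
  new_test_report(
    "Shapiro-Wilk normality",
    statistic = unname(sw$statistic), p_value = sw$p.value,
    n = length(x), alpha = alpha,
    note = NA_character_,
    extra = list(route = if (sw$p.value >= alpha) "parametric" else "nonparametric")
  )
}

#' Within-session comparison of first vs third condition
#'
#' Wilcoxon matched-pairs signed-rank test on per-participant correct-answer
#' counts between two conditions of the same sessions (default NM3 minus
#' NM1), asking whether accuracy improves from the first to the third block
#' of a session. Counts are summed over the selected sessions so the ranks
#' stay exact integers.
#'
#' @param acc An [accuracy_table()].
#' @param cond_a,cond_b Conditions compared (difference is `b - a`).
#' @param sessions Sessions to pool (default: all sessions where both
#'   conditions appear).
#' @param group Restrict to one group, or `NULL` for all participants.
#' @param alpha Significance level (default 0.05).
#' @return An `affect_test_report` (exact Wilcoxon, see [wilcoxon_exact()]).
#' @export
within_session_test <- function(acc, cond_a = "NM1", cond_b = "NM3",
                                sessions = NULL, group = NULL, alpha = 0.05) {
  if (!is.null(group)) {
    acc <- filter(acc, .data$group == !!group)
  }
  both <- acc %>%
    filter(.data$condition %in% c(cond_a, cond_b))
  if (is.null(sessions)) {
    per_session <- both %>%
      distinct(.data$session_index, .data$condition) %>%
      count(.data$session_index)
    sessions <- per_session$session_index[per_session$n == 2]
  }
  paired <- both %>%
    filter(.data$session_index %in% sessions) %>%
    group_by(.data$participant_id, .data$condition) %>%
    summarise(n_correct = sum(.data$n_correct), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "n_correct")
  if (!all(c(cond_a, cond_b) %in% names(paired)) ||
      any(!complete.cases(paired))) {
    abort("paired cells are incomplete: every participant needs both conditions.")
  }
  wilcoxon_exact(paired[[cond_b]] - paired[[cond_a]], alpha = alpha)
}

#' Across-session paired comparison of first vs final assessment
#'
#' Compares per-participant correct-answer counts of the first session's
#' first condition with the follow-up assessment (one week after the last
#' session) of the same condition, separately per group. With exactly two
#' repeated measures the repeated-measures comparison reduces to the paired
#' t-test (the ANOVA F equals t squared), which is how it is computed;
#' mean difference, SD and SE of the differences are all reported.
#'
#' @param acc An [accuracy_table()].
#' @param first_session,last_session Session indices compared (defaults 1
#'   and 5, the follow-up assessment slot).
#' @param condition Condition compared (default `"NM1"`).
#' @param alpha Significance level (default 0.05).
#' @return A tibble of class `across_session_report`, one row per group:
#'   `group`, `n`, `mean_diff`, `sd_diff`, `se_diff`, `statistic` (paired
#'   t), `df`, `p_value`, `significant`.
#' @export
across_session_test <- function(acc, first_session = 1L, last_session = 5L,
                                condition = "NM1", alpha = 0.05) {
  paired <- acc %>%
    filter(
      .data$condition == !!condition,
      .data$session_index %in% c(first_session, last_session)
    ) %>%
    mutate(which = ifelse(.data$session_index == first_session, "first", "last")) %>%
    select("participant_id", "group", "which", "n_correct") %>%
    tidyr::pivot_wider(names_from = "which", values_from = "n_correct")
  if (!all(c("first", "last") %in% names(paired)) ||
      any(!complete.cases(paired))) {
    abort("both sessions must be present for every participant.")
  }
  out <- paired %>%
    group_by(.data$group) %>%
    summarise(
      n = dplyr::n(),
      mean_diff = mean(.data$last - .data$first),
      sd_diff = sd(.data$last - .data$first),
      .groups = "drop"
    )
  if (any(out$n < 3)) {
    abort("each group needs at least 3 participants for the paired comparison.")
  }
  out <- out %>%
    mutate(
      se_diff = .data$sd_diff / sqrt(.data$n),
      statistic = ifelse(.data$sd_diff == 0 & .data$mean_diff == 0,
                         0, .data$mean_diff / .data$se_diff),
      df = .data$n - 1,
      p_value = ifelse(.data$sd_diff == 0 & .data$mean_diff == 0,
                       1, 2 * pt(-abs(.data$statistic), .data$n - 1)),
      significant = .data$p_value <= alpha
    )
  class(out) <- c("across_session_report", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "condition") <- condition
  out
}
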