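test_that("accuracy tallies are exact and duplicates are rejected", {
  sched <- build_schedule("EG01", "EG", 1, seed = 1)
  resp <- simulate_verbal_responses(sched, response_effect(1, 0), seed = 1)
  acc <- accuracy_table(resp)
  expect_true(all(acc$accuracy == 1))
  expect_true(all(acc$n_total == 12))

  resp$correct[resp$condition == "NM1"][1:3] <- FALSE
  acc2 <- accuracy_table(resp)
  expect_equal(acc2$n_correct[acc2$condition == "NM1"], 9)
  expect_equal(acc2$accuracy[acc2$condition == "NM1"], 0.75)

  expect_error(accuracy_table(rbind(resp, resp[1, ])), "duplicate")
  expect_warning(out <- accuracy_table(resp[0, ]), "empty")
  expect_equal(nrow(out), 0)
})

test_that("exact Wilcoxon p-values match full sign enumeration", {
  enumerate_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- signs %*% r
    p_le <- mean(ws <= w_obs + 1e-9)
    p_ge <- mean(ws >= w_obs - 1e-9)
    min(1, 2 * min(p_le, p_ge))
  }
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    d <- sample(-4:4, n, replace = TRUE) # plenty of ties and zeros
    if (all(d == 0)) d[1] <- 1
    got <- wilcoxon_exact(d)
    expect_equal(got$p_value, enumerate_p(d), tolerance = 1e-12,
                 label = sprintf("case %d", i))
  }
  # no ties: also matches the unconditional distribution used by wilcox.test
  d <- c(1.2, -0.7, 2.5, 3.1, -0.2, 0.9, 1.7, -2.2)
  ref <- stats::wilcox.test(d, exact = TRUE)$p.value
  expect_equal(wilcoxon_exact(d)$p_value, ref, tolerance = 1e-12)
})

test_that("uniform improvement across 14 participants hits the exact tail", {
  rep14 <- wilcoxon_exact(rep(1, 14) + c(rep(0, 7), rep(1, 7)))
  expect_equal(rep14$p_value, 2 / 2^14, tolerance = 1e-15)
  all_zero <- wilcoxon_exact(rep(0, 10))
  expect_equal(all_zero$p_value, 1)
  expect_match(all_zero$note, "zero")
})

test_that("the normality gate routes by Shapiro-Wilk at 0.05", {
  normal_pass <- vapply(1:100, function(s) {
    set.seed(s)
    normality_gate(rnorm(12))$p_value >= 0.05
  }, logical(1))
  expect_gte(mean(normal_pass), 0.90)

  skew_flag <- vapply(1:100, function(s) {
    set.seed(s)
    g <- normality_gate(rexp(14)^2) # heavily right-skewed sample
    g$p_value < 0.05 && g$route == "nonparametric" && g$statistic <= 1
  }, logical(1))
  expect_gte(mean(skew_flag), 0.80)

  expect_error(normality_gate(rep(2, 10)), "constant")
  expect_error(normality_gate(rnorm(2)), "between 3 and 50")
})

test_that("within-session comparison is null on identical conditions", {
  acc <- tidyr::expand_grid(
    participant_id = sprintf("P%02d", 1:8),
    session_index = 1:2,
    condition = c("NM1", "NM3")
  )
  acc$group <- "EG"
  set.seed(4)
  per_pair <- sample(4:11, 16, replace = TRUE)
  acc$n_correct <- rep(per_pair, each = 2) # NM1 == NM3 within each pair
  rep0 <- within_session_test(acc)
  expect_equal(rep0$p_value, 1)
  expect_equal(rep0$n, 0)

  # an all-positive shift is maximally significant
  acc$n_correct[acc$condition == "NM3"] <-
    acc$n_correct[acc$condition == "NM3"] + 1
  rep1 <- within_session_test(acc)
  expect_equal(rep1$p_value, 2 / 2^8, tolerance = 1e-12)
})

test_that("the across-session comparison equals the paired t-test and two-level ANOVA", {
  sch <- build_study_schedules(design_config(eg_size = 6, cg_size = 5), seed = 2)
  resp <- simulate_verbal_responses(sch, response_effect(0.5, 0.08), seed = 2)
  acc <- accuracy_table(resp)
  rep <- across_session_test(acc)
  for (g in c("EG", "CG")) {
    cell <- acc |>
      dplyr::filter(group == g, condition == "NM1",
                    session_index %in% c(1, 5)) |>
      dplyr::arrange(participant_id, session_index)
    first <- cell$n_correct[cell$session_index == 1]
    last <- cell$n_correct[cell$session_index == 5]
    tt <- stats::t.test(last, first, paired = TRUE)
    row <- rep[rep$group == g, ]
    expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(row$statistic, row$mean_diff / row$se_diff, tolerance = 1e-10)
    # two-measure repeated-measures ANOVA: F = t^2
    long <- data.frame(
      y = c(first, last),
      session = factor(rep(c("s1", "s5"), each = length(first))),
      pid = factor(rep(seq_along(first), 2))
    )
    an <- summary(stats::aov(y ~ session + Error(pid), data = long))
    f_val <- an[["Error: Within"]][[1]]["session", "F value"]
    expect_equal(f_val, unname(tt$statistic)^2, tolerance = 1e-8)
  }
})

test_that("a planted EG gain separates the groups' across-session outcomes", {
  sch <- build_study_schedules(design_config(), seed = 3)
  hits <- vapply(seq_len(100), function(s) {
    resp <- simulate_verbal_responses(sch, response_effect(0.5, 0.1), seed = s)
    rep <- across_session_test(accuracy_table(resp))
    rep$p_value[rep$group == "EG"] < 0.05 && rep$p_value[rep$group == "CG"] >= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})
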