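test_that("stratified folds are disjoint, exhaustive and balanced", {
  for (seed in 1:25) {
    y <- factor(sample(rep(emos, times = c(31, 17, 23, 40))))
    id <- stratified_folds(y, 5, seed = seed)
    expect_setequal(unique(id), 1:5)
    tab <- table(y, id)
    for (cl in rownames(tab)) {
      expect_lte(max(tab[cl, ]) - min(tab[cl, ]), 1)
    }
  }
  expect_error(stratified_folds(rep(emos, 2), 3, 1), "fewer instances")
  expect_error(stratified_folds(rep(emos, 5), 1, 1), "at least 2")
})

test_that("both classifiers master linearly separable clusters", {
  f <- cluster_features(n_per = 100, sep = 10, sd = 1, seed = 2)
  ann <- train_eval_ann(f, folds = 10, seed = 2)
  svm <- train_eval_linear_svm(f, folds = 10, seed = 2)
  expect_gte(ann$mean_accuracy, 0.95)
  expect_gte(svm$mean_accuracy, 0.95)
  expect_equal(sum(ann$confusion), ann$n_instances)
  expect_equal(unname(rowSums(ann$confusion)), rep(100, 4))
  expect_equal(ann$mean_accuracy, sum(diag(ann$confusion)) / ann$n_instances,
               tolerance = 1e-12)
})

test_that("label-permuted features decode at chance for both classifiers", {
  f <- chance_features(n = 600, seed = 3)
  ann <- train_eval_ann(f, folds = 10, repeats = 2, seed = 3)
  svm <- train_eval_linear_svm(f, folds = 10, repeats = 2, seed = 3)
  expect_gt(ann$mean_accuracy, 0.20)
  expect_lt(ann$mean_accuracy, 0.30)
  expect_gt(svm$mean_accuracy, 0.20)
  expect_lt(svm$mean_accuracy, 0.30)
})

test_that("chance-level accuracy tightens around 0.25 as n grows", {
  f <- chance_features(n = 4000, seed = 8)
  res <- train_eval_ann(f, folds = 10, seed = 8)
  expect_lt(abs(res$mean_accuracy - 0.25), 0.02)
})

test_that("the network beats the linear margin on an XOR class layout", {
  f <- xor_features(n_per = 40, seed = 1)
  ann <- train_eval_ann(f, folds = 10, seed = 1)
  svm <- train_eval_linear_svm(f, folds = 10, seed = 1)
  expect_lte(svm$mean_accuracy, 0.60)
  expect_gte(ann$mean_accuracy - svm$mean_accuracy, 0.15)
})

test_that("planted affect signal beats its own label permutation", {
  wins <- vapply(1:3, function(seed) {
    feats <- pipeline_features(seed = seed, background_uv = 0.3)
    z <- normalize_affect(feats)
    signal <- train_eval_ann(z, folds = 5, seed = seed)
    perm <- z
    set.seed(seed)
    perm$emotion <- sample(perm$emotion)
    null <- train_eval_ann(perm, folds = 5, seed = seed)
    signal$mean_accuracy > null$mean_accuracy
  }, logical(1))
  expect_true(all(wins))
})

test_that("decoding is reproducible and validates its inputs", {
  f <- chance_features(n = 200, seed = 4)
  r1 <- train_eval_ann(f, folds = 5, seed = 9)
  r2 <- train_eval_ann(f, folds = 5, seed = 9)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$confusion, r2$confusion)

  few <- f[c(which(f$emotion == "sad")[1:3],
             which(f$emotion != "sad")[1:60]), ]
  expect_error(train_eval_ann(few, folds = 5, seed = 1), "sad")
})

test_that("epoch-aggregated instances and epoch-grouped folds are supported", {
  feats <- pipeline_features(seed = 13, background_uv = 0.3)
  z <- normalize_affect(feats)
  agg <- train_eval_ann(z, folds = 3, seed = 1, instance = "epoch_mean")
  expect_equal(agg$n_instances, dplyr::n_distinct(z$stimulus_id))
  grouped <- train_eval_ann(z, folds = 3, seed = 1, fold_unit = "epoch")
  expect_equal(grouped$n_instances, nrow(z))
  expect_gte(grouped$mean_accuracy, 0.5) # planted signal survives grouping
})

test_that("model comparison behaves as an exact paired sign-flip test", {
  f <- cluster_features(n_per = 30, seed = 5)
  a <- train_eval_ann(f, folds = 10, seed = 5)
  self <- compare_models(a, a)
  expect_equal(self$p_value, 1)
  expect_equal(self$mean_diff, 0)

  b <- a
  b$fold_accuracy <- a$fold_accuracy - 0.2
  b$mean_accuracy <- mean(b$fold_accuracy)
  shifted <- compare_models(a, b, alpha = 0.05)
  expect_equal(shifted$p_value, 2 / 1024, tolerance = 1e-12)
  expect_true(shifted$significant)

  short <- a
  short$fold_accuracy <- a$fold_accuracy[1:5]
  expect_error(compare_models(a, short), "fold counts")
})

test_that("the comparison's false-positive rate matches its level", {
  set.seed(6)
  rej <- vapply(seq_len(200), function(i) {
    a <- eegaffect:::new_cv_result(runif(10, 0.2, 0.3), matrix(0, 4, 4),
                                   "ann", 10, 1, 100, i)
    b <- eegaffect:::new_cv_result(runif(10, 0.2, 0.3), matrix(0, 4, 4),
                                   "ann", 10, 1, 100, i)
    compare_models(a, b)$significant
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})
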