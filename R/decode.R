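#' Stratified fold assignment
#'
#' Assigns each instance to one of `folds` cross-validation folds such that
#' every class's instances are spread as evenly as possible: per-fold class
#' counts deviate from exact proportionality by at most one instance.
#'
#' @param y Factor (or vector) of class labels.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for the within-class shuffles.
#' @return Integer vector of fold ids in `1:folds`, one per instance.
#' @export
stratified_folds <- function(y, folds, seed = 1) {
  y <- as.factor(y)
  folds <- as.integer(folds)
  if (folds < 2) {
    abort("`folds` must be at least 2.")
  }
  counts <- table(y)
  too_small <- names(counts)[counts < folds]
  if (length(too_small)) {
    abort(sprintf(
      "class '%s' has fewer instances (%d) than folds (%d).",
      too_small[1], counts[[too_small[1]]], folds
    ))
  }
  id <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      id[idx] <- rep_len(sample(folds), length(idx))
    }
  })
  id
}

# ---- small feed-forward network ------------------------------------------

# 2-input, two 3-unit tanh hidden layers, 4-way softmax output, trained by
# full-batch gradient descent on cross-entropy with momentum and a
# bold-driver learning-rate schedule. Weights start from seeded uniform
# draws in [-0.5, 0.5].
mlp_fit <- function(x, y, hidden = c(3L, 3L), max_iter = 2000, tol = 1e-6,
                    lr = 0.2, momentum = 0.9, seed = 1) {
  x <- as.matrix(x)
  y <- as.factor(y)
  n <- nrow(x)
  k <- nlevels(y)
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  target <- matrix(0, n, k)
  target[cbind(seq_len(n), as.integer(y))] <- 1

  dims <- c(ncol(x), hidden, k)
  with_seed(seed, {
    w <- lapply(seq_len(length(dims) - 1), function(l) {
      matrix(runif(dims[l] * dims[l + 1], -0.5, 0.5), dims[l], dims[l + 1])
    })
    b <- lapply(seq_len(length(dims) - 1), function(l) {
      runif(dims[l + 1], -0.5, 0.5)
    })
  })
  vw <- lapply(w, function(m) m * 0)
  vb <- lapply(b, function(v) v * 0)

  forward <- function(w, b) {
    h1 <- tanh(sweep(xs %*% w[[1]], 2, b[[1]], "+"))
    h2 <- tanh(sweep(h1 %*% w[[2]], 2, b[[2]], "+"))
    s <- sweep(h2 %*% w[[3]], 2, b[[3]], "+")
    s <- s - apply(s, 1, max)
    e <- exp(s)
    p <- e / rowSums(e)
    list(h1 = h1, h2 = h2, p = p)
  }

  loss_of <- function(p) -mean(log(pmax(p[cbind(seq_len(n), as.integer(y))], 1e-12)))

  fw <- forward(w, b)
  loss <- loss_of(fw$p)
  stall <- 0
  for (iter in seq_len(max_iter)) {
    # backprop (gradients of mean cross-entropy)
    d3 <- (fw$p - target) / n
    gw3 <- crossprod(fw$h2, d3)
    gb3 <- colSums(d3)
    d2 <- (d3 %*% t(w[[3]])) * (1 - fw$h2^2)
    gw2 <- crossprod(fw$h1, d2)
    gb2 <- colSums(d2)
    d1 <- (d2 %*% t(w[[2]])) * (1 - fw$h1^2)
    gw1 <- crossprod(xs, d1)
    gb1 <- colSums(d1)
    gw <- list(gw1, gw2, gw3)
    gb <- list(gb1, gb2, gb3)

    for (l in 1:3) {
      vw[[l]] <- momentum * vw[[l]] - lr * gw[[l]]
      vb[[l]] <- momentum * vb[[l]] - lr * gb[[l]]
    }
    w_new <- Map(`+`, w, vw)
    b_new <- Map(`+`, b, vb)
    fw_new <- forward(w_new, b_new)
    loss_new <- loss_of(fw_new$p)

    if (is.finite(loss_new) && loss_new <= loss + 1e-12) {
      delta <- loss - loss_new
      w <- w_new
      b <- b_new
      fw <- fw_new
      lr <- min(lr * 1.05, 1)
      if (delta < tol * max(1, abs(loss_new))) stall <- stall + 1 else stall <- 0
      loss <- loss_new
      if (stall >= 10) break
    } else {
      # overshoot: halve the step and damp the velocity
      lr <- lr / 2
      vw <- lapply(vw, function(m) m * 0.5)
      vb <- lapply(vb, function(v) v * 0.5)
      if (lr < 1e-8) break
    }
  }
  structure(
    list(
      w = w, b = b, center = center, scale = scale, levels = levels(y),
      loss = loss, iter = iter
    ),
    class = "eegaffect_mlp"
  )
}

#' @export
predict.eegaffect_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  h1 <- tanh(sweep(xs %*% object$w[[1]], 2, object$b[[1]], "+"))
  h2 <- tanh(sweep(h1 %*% object$w[[2]], 2, object$b[[2]], "+"))
  s <- sweep(h2 %*% object$w[[3]], 2, object$b[[3]], "+")
  s <- s - apply(s, 1, max)
  p <- exp(s) / rowSums(exp(s))
  colnames(p) <- object$levels
  if (type == "prob") {
    return(p)
  }
  factor(object$levels[max.col(p, ties.method = "first")], levels = object$levels)
}

# ---- cross-validation engine ---------------------------------------------

prepare_instances <- function(features, instance = c("window", "epoch_mean")) {
  instance <- match.arg(instance)
  req <- c("arousal", "valence", "emotion")
  missing <- setdiff(req, names(features))
  if (length(missing)) {
    abort(paste0("features lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (instance == "epoch_mean") {
    if (!"stimulus_id" %in% names(features)) {
      abort("epoch_mean aggregation needs a `stimulus_id` column.")
    }
    features <- features %>%
      group_by(.data$stimulus_id, .data$emotion) %>%
      summarise(
        arousal = mean(.data$arousal), valence = mean(.data$valence),
        .groups = "drop"
      )
  }
  list(
    x = cbind(arousal = features$arousal, valence = features$valence),
    y = factor(features$emotion, levels = emotion_levels),
    epoch = if ("stimulus_id" %in% names(features)) features$stimulus_id else NULL
  )
}

cv_engine <- function(x, y, folds, repeats, seed, fit_fun, tag,
                      fold_unit = "instance", epoch = NULL) {
  n <- nrow(x)
  k <- nlevels(y)
  fold_acc <- numeric(0)
  confusion <- matrix(0, k, k, dimnames = list(true = levels(y), predicted = levels(y)))
  for (r in seq_len(repeats)) {
    rep_seed <- derive_seed(seed, r)
    if (fold_unit == "epoch" && !is.null(epoch)) {
      ep <- unique(epoch)
      ep_class <- y[match(ep, epoch)]
      ep_fold <- stratified_folds(ep_class, folds, seed = rep_seed)
      fold_id <- ep_fold[match(epoch, ep)]
    } else {
      fold_id <- stratified_folds(y, folds, seed = rep_seed)
    }
    for (f in seq_len(folds)) {
      test <- fold_id == f
      model <- fit_fun(x[!test, , drop = FALSE], droplevels(y[!test]),
                       seed = derive_seed(rep_seed, f))
      pred <- predict(model, x[test, , drop = FALSE])
      pred <- factor(as.character(pred), levels = levels(y))
      fold_acc <- c(fold_acc, mean(pred == y[test]))
      confusion <- confusion + table(y[test], pred)
    }
  }
  new_cv_result(
    fold_accuracy = fold_acc,
    confusion = confusion / repeats,
    classifier = tag,
    folds = folds,
    repeats = repeats,
    n_instances = n,
    seed = seed
  )
}

new_cv_result <- function(fold_accuracy, confusion, classifier, folds,
                          repeats, n_instances, seed) {
  structure(
    list(
      fold_accuracy = fold_accuracy,
      mean_accuracy = mean(fold_accuracy),
      confusion = confusion,
      classifier = classifier,
      folds = folds,
      repeats = repeats,
      n_instances = n_instances,
      seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s: mean accuracy %.3f over %d x %d-fold CV (n = %d)\n",
    x$classifier, x$mean_accuracy, x$repeats, x$folds, x$n_instances
  ))
  invisible(x)
}

#' Four-class emotion decoding with a small neural network
#'
#' Trains and evaluates a feed-forward network with a 2-node input layer
#' (arousal, valence), two 3-node tanh hidden layers and a 4-node softmax
#' output (one per emotion) under stratified `folds`-fold cross-validation,
#' optionally repeated over several random fold assignments. Folds are
#' disjoint, exhaustive, and preserve class proportions to within one
#' instance. The entire procedure is deterministic given `seed`.
#'
#' @param features An [epoch_feature_set][epoch_affect()] (or any tibble
#'   with `arousal`, `valence`, `emotion`), normally z-scored via
#'   [normalize_affect()]. All four emotions must be present with at least
#'   `folds` instances each.
#' @param folds Number of CV folds (default 10).
#' @param repeats Number of repeated fold assignments to average (default 1).
#' @param seed Integer seed.
#' @param instance `"window"` (default: one instance per instantaneous
#'   feature window) or `"epoch_mean"` (one instance per stimulus epoch,
#'   features averaged within the epoch).
#' @param fold_unit `"instance"` (default) or `"epoch"` (keep all windows of
#'   one stimulus in the same fold, avoiding within-epoch leakage).
#' @param max_iter,tol Training iteration cap and relative loss tolerance.
#' @return A `cv_result`: per-fold accuracies, mean accuracy, 4x4 confusion
#'   matrix (averaged over repeats), classifier tag, `n_instances`, `seed`.
#'   Use [tidy()] / [glance()] for tabular views.
#' @examples
#' feats <- tibble::tibble(
#'   arousal = rnorm(80), valence = rnorm(80),
#'   emotion = rep(c("happy", "sad", "angry", "fear"), 20)
#' )
#' train_eval_ann(feats, folds = 5, seed = 1)
#' @export
train_eval_ann <- function(features, folds = 10, repeats = 1, seed = 1,
                           instance = c("window", "epoch_mean"),
                           fold_unit = c("instance", "epoch"),
                           max_iter = 2000, tol = 1e-6) {
  inst <- prepare_instances(features, match.arg(instance))
  fold_unit <- match.arg(fold_unit)
  fit_fun <- function(x, y, seed) {
    mlp_fit(x, y, max_iter = max_iter, tol = tol, seed = seed)
  }
  cv_engine(inst$x, inst$y, folds, repeats, seed, fit_fun, "ann",
            fold_unit = fold_unit, epoch = inst$epoch)
}

#' Four-class emotion decoding with a linear-kernel SVM
#'
#' Maximum-margin linear classifier baseline for the same task as
#' [train_eval_ann()], used to probe whether the emotions are linearly
#' separable in the arousal-valence plane.
#'
#' @inheritParams train_eval_ann
#' @param cost SVM cost parameter (default 1).
#' @return A `cv_result` with `classifier = "linear_svm"`.
#' @export
train_eval_linear_svm <- function(features, folds = 10, repeats = 1, seed = 1,
                                  instance = c("window", "epoch_mean"),
                                  fold_unit = c("instance", "epoch"),
                                  cost = 1) {
  inst <- prepare_instances(features, match.arg(instance))
  fold_unit <- match.arg(fold_unit)
  fit_fun <- function(x, y, seed) {
    with_seed(seed, e1071::svm(x, y, kernel = "linear", cost = cost, scale = TRUE))
  }
  cv_engine(inst$x, inst$y, folds, repeats, seed, fit_fun, "linear_svm",
            fold_unit = fold_unit, epoch = inst$epoch)
}

#' Paired comparison of two cross-validated models
#'
#' Exact paired sign-flip permutation test on the per-fold accuracy
#' differences of two `cv_result`s evaluated with the same fold structure
#' (for 10 folds, all 1024 sign assignments are enumerated; above 20 folds a
#' seeded Monte-Carlo sample of flips is used). The statistic is the mean
#' accuracy difference.
#'
#' @param a,b `cv_result` objects with equally many folds.
#' @param alpha Significance level (default 0.05).
#' @param n_mc Monte-Carlo flips used beyond 20 folds.
#' @param seed Seed for the Monte-Carlo branch.
#' @return A list of class `comparison_report`: `mean_diff`, `p_value`,
#'   `significant`, `n_folds`, `method`.
#' @export
compare_models <- function(a, b, alpha = 0.05, n_mc = 10000, seed = 1) {
  stopifnot(inherits(a, "cv_result"), inherits(b, "cv_result"))
  if (length(a$fold_accuracy) != length(b$fold_accuracy)) {
    abort("the two results have different fold counts; they are not comparable.")
  }
  d <- a$fold_accuracy - b$fold_accuracy
  n <- length(d)
  obs <- mean(d)
  eps <- 1e-12
  if (n <= 20) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- as.vector(signs %*% d) / n
    p <- mean(abs(perm) >= abs(obs) - eps)
    method <- "exact sign-flip permutation"
  } else {
    perm <- with_seed(seed, {
      vapply(seq_len(n_mc), function(i) {
        mean(d * sample(c(-1, 1), n, replace = TRUE))
      }, numeric(1))
    })
    p <- (sum(abs(perm) >= abs(obs) - eps) + 1) / (n_mc + 1)
    method <- "Monte-Carlo sign-flip permutation"
  }
  structure(
    list(
      mean_diff = obs,
      p_value = p,
      alpha = alpha,
      significant = p <= alpha,
      n_folds = n,
      method = method,
      classifiers = c(a$classifier, b$classifier)
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report> %s vs %s: mean accuracy difference %+.3f, p = %.4g (%s)\n",
    x$classifiers[1], x$classifiers[2], x$mean_diff, x$p_value, x$method
  ))
  invisible(x)
}
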