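#' Root-mean-square error
#' @param pred,truth equal-length numeric vectors.
#' @return nonnegative scalar.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stop("pred and truth must be nonempty and of equal length")
  sqrt(mean((pred - truth)^2))
}

#' Classification error rate
#' @param pred_labels,truth equal-length label vectors.
#' @return fraction mismatched, in \[0, 1\].
#' @export
class_error <- function(pred_labels, truth) {
  if (length(pred_labels) == 0 || length(pred_labels) != length(truth))
    stop("pred_labels and truth must be nonempty and of equal length")
  mean(pred_labels != truth)
}

check_binary_labels <- function(labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  labels
}

#' ROC AUC (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive is scored above a
#' randomly chosen negative, with ties counted 1/2 — computed via midranks,
#' which is exactly equal to pairwise counting.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Standard error from the Hanley-McNeil moments
#' `Q1 = A/(2 - A)`, `Q2 = 2*A^2/(1 + A)`;
#' the 95% interval is `A +/- 1.96 * SE`, clipped to \[0, 1\].
#'
#' @param auc AUC estimate in \[0, 1\].
#' @param n_pos,n_neg class sizes (>= 1).
#' @return list with `low`, `high` and `se`.
#' @export
auc_ci <- function(auc, n_pos, n_neg) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
              (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  list(low = max(0, auc - 1.96 * se), high = min(1, auc + 1.96 * se),
       se = se)
}

#' ROC curve points
#'
#' One (fpr, tpr) point per distinct score cut (samples are classified
#' positive at or above the cut), prepended with (0, 0); the final point is
#' (1, 1). Both coordinates are monotone nondecreasing.
#'
#' @inheritParams roc_auc
#' @return data frame with columns `fpr` and `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  keep <- c(s[-length(s)] != s[-1], TRUE)  # last index of each tied block
  tp <- cumsum(l)[keep]
  fp <- cumsum(1 - l)[keep]
  data.frame(fpr = c(0, fp / sum(labels == 0)),
             tpr = c(0, tp / sum(labels == 1)))
}

#' Youden-optimal threshold
#'
#' Scans the observed score values as cut-points (classify positive when
#' `score >= threshold`) and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1; ties resolve to the lower threshold.
#'
#' @inheritParams roc_auc
#' @return list with `threshold`, `sensitivity`, `specificity`, `accuracy`
#'   and `j`.
#' @export
optimal_threshold <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  cuts <- sort(unique(scores))
  best <- NULL
  for (t in cuts) {
    pred <- as.numeric(scores >= t)
    sens <- sum(pred == 1 & labels == 1) / n_pos
    spec <- sum(pred == 0 & labels == 0) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   accuracy = mean(pred == labels), j = j)
    }
  }
  best
}

#' Full ROC summary for one score vector
#'
#' Bundles [roc_auc()], its Hanley-McNeil 95% CI, the Youden-optimal
#' operating point and the ROC curve.
#'
#' @inheritParams roc_auc
#' @return a list of class `roc_result`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  a <- roc_auc(scores, labels)
  ci <- auc_ci(a, sum(labels == 1), sum(labels == 0))
  opt <- optimal_threshold(scores, labels)
  structure(list(auc = a, ci_low = ci$low, ci_high = ci$high,
                 threshold = opt$threshold, sensitivity = opt$sensitivity,
                 specificity = opt$specificity, accuracy = opt$accuracy,
                 curve = roc_curve(scores, labels)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (95%% CI [%.4f, %.4f])\n", x$auc, x$ci_low,
              x$ci_high))
  cat(sprintf("Youden threshold %.4g: sens %.4f, spec %.4f, acc %.4f\n",
              x$threshold, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Deterministic (stratified) cross-validation folds
#'
#' Regression folds are a random balanced partition (sizes differ by at most
#' 1). Classification folds are stratified: each class is shuffled and dealt
#' cyclically, continuing the cycle across classes, so class ratios are
#' preserved within one sample and overall sizes stay balanced. Requires
#' each class to appear at least `k` times so no fold is ever single-class.
#'
#' @param y target vector.
#' @param k number of folds (2..n).
#' @param task `"regression"` or `"classification"`.
#' @param seed integer seed (folds are a pure function of `(y, k, seed)`).
#' @return integer vector of fold labels in `1..k`.
#' @export
make_folds <- function(y, k, task, seed = 1) {
  n <- length(y)
  stopifnot(k >= 2, k <= n)
  withr::with_seed(as.integer(seed), {
    fold <- integer(n)
    if (task == "classification") {
      cls <- unique(y)
      counts <- table(y)
      if (min(counts) < k)
        stop("stratification impossible: smallest class has ",
             min(counts), " samples but k = ", k)
      offset <- 0L
      for (cl in cls) {
        idx <- sample(which(y == cl))
        fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
        offset <- offset + length(idx)
      }
    } else {
      fold <- sample(rep(seq_len(k), length.out = n))
    }
    fold
  })
}

#' k-fold cross-validation
#'
#' Deterministic seeded fold assignment ([make_folds()], stratified for
#' classification), one fit per fold, and per-fold plus mean metrics:
#' RMSE for regression; AUC with Hanley-McNeil CI, Youden-threshold
#' sensitivity/specificity/accuracy for classification.
#'
#' @param X feature matrix.
#' @param y target vector (0/1 for classification).
#' @param k number of folds (default 10).
#' @param task `"regression"` or `"classification"`.
#' @param fit_fun `function(X_train, y_train)` returning a model.
#' @param predict_fun `function(model, X_test)` returning predictions
#'   (scores/probabilities for classification).
#' @param seed integer seed for the fold assignment.
#' @return a list of class `cv_result` with `folds` (per-fold data frame),
#'   `mean` (named vector of fold means) and `assignments`.
#' @export
kfold_cv <- function(X, y, k = 10, task = c("regression", "classification"),
                     fit_fun, predict_fun, seed = 1) {
  task <- match.arg(task)
  X <- as.matrix(X)
  fold <- make_folds(y, k, task, seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    model <- fit_fun(X[tr, , drop = FALSE], y[tr])
    pred <- predict_fun(model, X[te, , drop = FALSE])
    if (task == "regression") {
      rows[[f]] <- data.frame(fold = f, n_test = length(te),
                              rmse = rmse(pred, y[te]))
    } else {
      r <- roc_analysis(pred, y[te])
      rows[[f]] <- data.frame(fold = f, n_test = length(te), auc = r$auc,
                              ci_low = r$ci_low, ci_high = r$ci_high,
                              sensitivity = r$sensitivity,
                              specificity = r$specificity,
                              accuracy = r$accuracy)
    }
  }
  folds <- do.call(rbind, rows)
  metric_cols <- setdiff(names(folds), c("fold", "n_test"))
  structure(list(folds = folds, mean = colMeans(folds[metric_cols]),
                 assignments = fold, k = k, task = task),
            class = "cv_result")
}

#' Paired Wilcoxon signed-rank test
#'
#' The convention used for method comparisons on benchmark tables: zero
#' differences are dropped, absolute differences are ranked with midranks,
#' W is the sum of positive-difference ranks, and the p-value comes from the
#' normal approximation with tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48` and a 0.5 continuity correction.
#' All-zero differences give p = 1.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative `"two_sided"`, `"less"` (x tends below y) or
#'   `"greater"`.
#' @return list with `statistic` (W), `p`, `n` (nonzero pairs) and `z`.
#' @examples
#' wilcoxon_paired(c(1, 2, 3), c(2, 2, 2))$p
#' @export
wilcoxon_paired <- function(x, y,
                            alternative = c("two_sided", "less",
                                            "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0) stop("x and y must be nonempty")
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p = 1, n = 0L, z = 0))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)  # equal |d| share one midrank value
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0)
    return(list(statistic = w, p = 1, n = n, z = 0))
  sigma <- sqrt(sigma2)
  z <- switch(alternative,
              two_sided = (w - mu - sign(w - mu) * 0.5) / sigma,
              greater = (w - mu - 0.5) / sigma,
              less = (w - mu + 0.5) / sigma)
  p <- switch(alternative,
              two_sided = min(1, 2 * pnorm(-abs(z))),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  list(statistic = w, p = p, n = n, z = z)
}
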