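test_that("rmse and classification error match their definitions", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  expect_equal(class_error(c(0, 1), c(0, 1)), 0)
  expect_equal(class_error(c(0, 0), c(0, 1)), 0.5)
  expect_error(rmse(numeric(0), numeric(0)), "nonempty")
  expect_error(class_error(1, c(1, 2)), "equal length")
})

test_that("roc_auc equals pairwise counting with the ties rule", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 0, 1)), 0.5)
  expect_equal(roc_auc(rep(0.5, 10), c(rep(1, 5), rep(0, 5))), 0.5)
  expect_equal(roc_auc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(21)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels),
                 tolerance = 0)
  }
})

test_that("Hanley-McNeil intervals behave at the boundaries and shrink", {
  ci1 <- auc_ci(1, 10, 20)
  expect_equal(ci1$se, 0)
  expect_equal(c(ci1$low, ci1$high), c(1, 1))

  ci5 <- auc_ci(0.5, 30, 30)
  expect_equal(0.5 - ci5$low, ci5$high - 0.5, tolerance = 1e-12)

  # independent evaluation of the same published formula
  A <- 0.7; na <- 431; nn <- 702
  q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (na - 1) * (q1 - A^2) + (nn - 1) * (q2 - A^2)) /
             (na * nn))
  got <- auc_ci(A, na, nn)
  expect_equal(got$se, se, tolerance = 1e-10)
  expect_equal(got$low, A - 1.96 * se, tolerance = 1e-10)

  widths <- vapply(c(50, 200, 1000, 5000), function(n) {
    ci <- auc_ci(0.7, n, n); ci$high - ci$low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(22)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.5)
  labels[1:2] <- c(0, 1)
  cv <- roc_curve(scores, labels)
  expect_equal(unlist(cv[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(cv[nrow(cv), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("the Youden-optimal threshold maximizes J", {
  perfect <- optimal_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)

  pair <- optimal_threshold(c(0.3, 0.6), c(0, 1))
  expect_equal(pair$j, 1)

  set.seed(23)
  for (rep in 1:20) {
    scores <- round(rnorm(40), 1)
    labels <- c(0, 1, rbinom(38, 1, 0.5))
    got <- optimal_threshold(scores, labels)
    # brute force over all cuts
    js <- vapply(sort(unique(scores)), function(t) {
      pred <- as.numeric(scores >= t)
      sum(pred == 1 & labels == 1) / sum(labels == 1) +
        sum(pred == 0 & labels == 0) / sum(labels == 0) - 1
    }, numeric(1))
    expect_equal(got$j, max(js), tolerance = 1e-12)
    expect_equal(got$threshold,
                 min(sort(unique(scores))[js > max(js) - 1e-12]))
  }
})

test_that("fold construction partitions, balances and stratifies", {
  y <- rnorm(47)
  f <- make_folds(y, 10, "regression", seed = 2)
  expect_equal(sort(unique(f)), 1:10)
  expect_lte(diff(range(table(f))), 1)

  # leave-one-out bookkeeping
  loo <- make_folds(y, length(y), "regression", seed = 2)
  expect_true(all(table(loo) == 1))

  for (s in 1:20) {
    yc <- rbinom(83, 1, 0.35)
    yc[1:20] <- rep(c(0, 1), 10)
    f <- make_folds(yc, 5, "classification", seed = s)
    tab <- table(f, yc)
    expect_true(all(abs(tab[, 2] - sum(yc) / 5) <= 1))
    expect_true(all(tab > 0))  # no single-class fold
  }
  expect_error(make_folds(c(rep(0, 30), 1, 1), 5, "classification"),
               "stratification")
})

test_that("cross-validation reports per-fold and mean metrics", {
  set.seed(24)
  X <- matrix(rnorm(200), 100, 2)
  y <- X[, 1] + rnorm(100, 0, 0.1)
  cv <- kfold_cv(X, y, k = 5, task = "regression", fit_fun = mean_fit,
                 predict_fun = mean_predict, seed = 3)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(sum(cv$folds$n_test), 100)
  expect_equal(cv$mean[["rmse"]], mean(cv$folds$rmse))

  d <- gen_oblique(120, d = 3, seed = 9)
  cvc <- kfold_cv(d$X, d$y, k = 4, task = "classification",
                  fit_fun = function(X, y)
                    rbforest:::fit_logistic_learner(X, y),
                  predict_fun = function(m, X)
                    rbforest:::predict_logistic_learner(m, X),
                  seed = 4)
  expect_true(all(c("auc", "sensitivity", "specificity", "accuracy")
                  %in% names(cvc$mean)))
  expect_true(all(cvc$folds$ci_low <= cvc$folds$auc &
                    cvc$folds$auc <= cvc$folds$ci_high))
  expect_gt(cvc$mean[["auc"]], 0.8)  # a linear task logistic must ace
})

test_that("the paired signed-rank test follows the stated conventions", {
  x <- rnorm(8)
  expect_equal(wilcoxon_paired(x, x)$p, 1)

  # antisymmetry: swapping the vectors swaps the one-sided alternatives
  set.seed(25)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(wilcoxon_paired(a, b, "less")$p,
               wilcoxon_paired(b, a, "greater")$p)
  expect_error(wilcoxon_paired(1:3, 1:4), "equal length")

  # agreement with the reference normal-approximation implementation,
  # including midranks for ties and the continuity correction
  for (s in 1:20) {
    set.seed(30 + s)
    x <- round(rnorm(14), 1)
    y <- round(rnorm(14), 1)
    for (alt in c("two_sided", "less", "greater")) {
      skip_p <- suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                           correct = TRUE,
                           alternative = sub("_sided", ".sided",
                                             alt))$p.value)
      expect_equal(wilcoxon_paired(x, y, alt)$p, skip_p,
                   tolerance = 1e-12)
    }
  }

  # normal approximation stays inside its error band vs exact enumeration
  for (s in 1:5) {
    set.seed(40 + s)
    x <- rnorm(12)
    y <- rnorm(12)
    approx_p <- wilcoxon_paired(x, y, "less")$p
    exact_p <- exact_wilcoxon_p(x, y, "less")
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("the published benchmark table reproduces its printed p-value", {
  b <- benchmark_rmse()
  expect_equal(nrow(b), 14)
  w <- wilcoxon_paired(b$rbf, b$rf, alternative = "less")
  expect_equal(w$n, 10)  # four zero differences dropped
  expect_equal(w$p, 0.007185, tolerance = 0.0005 / 0.007185)
})
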