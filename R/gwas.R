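#' Allelic association test for one SNP
#'
#' Builds the 2x2 allele-count table (each subject contributes two alleles:
#' `a` = case minor alleles, `b` = case major, `c` = control minor,
#' `d` = control major) and computes the chi-square statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with `N = a+b+c+d`, its p-value
#' on 1 df, the unadjusted odds ratio `ad / (bc)` (missing when any cell is
#' zero) and the squared Pearson correlation between genotype dosage and
#' phenotype. A zero allele marginal gives chi2 = 0 (and p = 1).
#'
#' @param genotypes vector in 0/1/2 (minor-allele counts).
#' @param phenotype 0/1 vector, both classes present.
#' @return list with `chi2`, `p`, `odds_ratio`, `r_squared`.
#' @export
allelic_assoc <- function(genotypes, phenotype) {
  res <- assoc_table(matrix(as.numeric(genotypes), ncol = 1), phenotype)
  list(chi2 = res$chi2[1], p = res$p[1], odds_ratio = res$odds_ratio[1],
       r_squared = res$r_squared[1])
}

#' Allelic association table for a genotype matrix
#'
#' Vectorized [allelic_assoc()] over the columns of `G`.
#'
#' @param G genotype matrix in 0/1/2, one SNP per column.
#' @param phenotype 0/1 vector, both classes present.
#' @return data frame with one row per SNP: `snp_index`, `snp` (column
#'   name), `chi2`, `p`, `odds_ratio`, `r_squared`.
#' @export
assoc_table <- function(G, phenotype) {
  G <- as.matrix(G)
  phenotype <- check_binary_labels(phenotype)
  if (nrow(G) != length(phenotype))
    stop("G and phenotype disagree on the number of subjects")
  if (!all(G %in% c(0, 1, 2)))
    stop("genotypes must be coded 0/1/2")
  case <- phenotype == 1
  n_case <- sum(case)
  n_ctrl <- sum(!case)
  a <- colSums(G[case, , drop = FALSE])        # case minor alleles
  b <- 2 * n_case - a                          # case major
  cc <- colSums(G[!case, , drop = FALSE])      # control minor
  d <- 2 * n_ctrl - cc                         # control major
  N <- a + b + cc + d
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi2 <- ifelse(denom > 0, N * (a * d - b * cc)^2 / denom, 0)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  or <- ifelse(a > 0 & b > 0 & cc > 0 & d > 0, a * d / (b * cc), NA_real_)
  sg <- apply(G, 2, sd)
  r2 <- rep(NA_real_, ncol(G))
  ok <- sg > 0
  if (any(ok))
    r2[ok] <- drop(stats::cor(G[, ok, drop = FALSE], phenotype))^2
  data.frame(snp_index = seq_len(ncol(G)),
             snp = if (is.null(colnames(G)))
               as.character(seq_len(ncol(G))) else colnames(G),
             chi2 = chi2, p = p, odds_ratio = or, r_squared = r2,
             row.names = NULL)
}

#' Rank SNPs by allelic association p-value
#'
#' Stable ascending sort by p-value, ties broken by ascending column index.
#'
#' @inheritParams assoc_table
#' @return integer vector of SNP column indices, strongest first.
#' @export
rank_snps <- function(G, phenotype) {
  at <- assoc_table(G, phenotype)
  order(at$p, at$snp_index)
}

fit_logistic_learner <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  coef
}

predict_logistic_learner <- function(coef, X) {
  stats::plogis(drop(cbind(1, as.matrix(X)) %*% coef))
}

gwas_learner_funs <- function(learner, rbf_args, seed) {
  if (learner == "logistic") {
    list(fit = fit_logistic_learner,
         predict = predict_logistic_learner)
  } else {
    list(fit = function(X, y) {
           do.call(rbf_fit, c(list(X = X, y = y, task = "classification",
                                   seed = seed), rbf_args))
         },
         predict = function(model, X) predict(model, X, type = "prob"))
  }
}

#' Sweep the number of top-ranked SNPs
#'
#' Ranks SNPs on the training cohort only, then for each `k` in `k_grid`
#' fits the learner on the top-`k` training SNPs and scores the AUC on the
#' independent test cohort; `best_k` maximizes test AUC (ties go to the
#' smaller `k`). Selecting `k` on the test set is optimistically biased —
#' the returned object carries that caveat and the print method repeats it.
#'
#' @param train,test lists with elements `G` (0/1/2 genotype matrix, same
#'   SNP columns in both) and `y` (0/1 phenotype).
#' @param k_grid candidate SNP counts; default `seq(5, 100, by = 5)`.
#' @param learner `"logistic"` (fast; the usual screening choice) or
#'   `"rbf"`.
#' @param rbf_args list of extra arguments for [rbf_fit()] when
#'   `learner = "rbf"`.
#' @param seed integer seed passed to the learner.
#' @return an object of class `gwas_sweep`: data frame `results`
#'   (`k`, `auc`), `best_k`, the training `ranking` and a `caveat` string.
#' @export
sweep_k <- function(train, test, k_grid = seq(5, 100, by = 5),
                    learner = c("logistic", "rbf"), rbf_args = list(),
                    seed = 1) {
  learner <- match.arg(learner)
  m <- ncol(train$G)
  if (ncol(test$G) != m)
    stop("train and test genotype matrices must share SNP columns")
  ranking <- rank_snps(train$G, train$y)
  funs <- gwas_learner_funs(learner, rbf_args, seed)
  keep <- k_grid <= m
  if (any(!keep))
    warning("dropping k > ", m, " from k_grid: ",
            paste(k_grid[!keep], collapse = ", "))
  k_grid <- k_grid[keep]
  if (length(k_grid) == 0) stop("k_grid is empty after removing k > m")
  auc <- vapply(k_grid, function(k) {
    cols <- ranking[seq_len(k)]
    model <- funs$fit(train$G[, cols, drop = FALSE], train$y)
    roc_auc(funs$predict(model, test$G[, cols, drop = FALSE]), test$y)
  }, numeric(1))
  best_k <- k_grid[which.max(auc)]  # which.max returns the first maximum
  structure(list(results = data.frame(k = k_grid, auc = auc),
                 best_k = best_k, ranking = ranking, learner = learner,
                 caveat = paste("best_k was chosen on the independent test",
                                "set; the selected test AUC is",
                                "optimistically biased")),
            class = "gwas_sweep")
}

#' @export
print.gwas_sweep <- function(x, ...) {
  cat(sprintf("<gwas_sweep (%s learner): best_k = %d (test AUC %.4f)>\n",
              x$learner, x$best_k,
              x$results$auc[x$results$k == x$best_k]))
  cat("note:", x$caveat, "\n")
  invisible(x)
}

#' Final GWAS prediction report
#'
#' For a fixed marker count `k` (typically a [sweep_k()] `best_k`): 10-fold
#' stratified cross-validation on the training cohort (mean AUC,
#' sensitivity, specificity, accuracy, and the range of the per-fold
#' Hanley-McNeil CIs) plus independent-test metrics at the Youden-optimal
#' threshold, with both ROC curves. SNPs are ranked on the training cohort
#' only.
#'
#' @inheritParams sweep_k
#' @param k number of top-ranked SNPs to use.
#' @param k_cv cross-validation folds (default 10).
#' @return an object of class `gwas_report` with `cv` (a [kfold_cv()]
#'   result), `cv_ci` (range of per-fold CIs), `test` (a [roc_analysis()]
#'   result) and `snps` (the SNP column indices used).
#' @export
gwas_report <- function(train, test, k, learner = c("rbf", "logistic"),
                        rbf_args = list(), k_cv = 10, seed = 1) {
  learner <- match.arg(learner)
  ranking <- rank_snps(train$G, train$y)
  if (k > length(ranking)) stop("k exceeds the number of SNPs")
  cols <- ranking[seq_len(k)]
  funs <- gwas_learner_funs(learner, rbf_args, seed)
  cv <- kfold_cv(train$G[, cols, drop = FALSE], train$y, k = k_cv,
                 task = "classification", fit_fun = funs$fit,
                 predict_fun = funs$predict, seed = seed)
  model <- funs$fit(train$G[, cols, drop = FALSE], train$y)
  test_roc <- roc_analysis(funs$predict(model, test$G[, cols, drop = FALSE]),
                           test$y)
  structure(list(cv = cv,
                 cv_ci = c(low = min(cv$folds$ci_low),
                           high = max(cv$folds$ci_high)),
                 test = test_roc, k = k, snps = cols, learner = learner),
            class = "gwas_report")
}

#' @export
print.gwas_report <- function(x, ...) {
  cat(sprintf("GWAS prediction report (%s learner, top %d SNPs)\n",
              x$learner, x$k))
  cat(sprintf(" training %d-fold CV: AUC %.4f (CI range [%.4f, %.4f]), ",
              x$cv$k, x$cv$mean[["auc"]], x$cv_ci[["low"]],
              x$cv_ci[["high"]]))
  cat(sprintf("sens %.4f, spec %.4f, acc %.4f\n",
              x$cv$mean[["sensitivity"]], x$cv$mean[["specificity"]],
              x$cv$mean[["accuracy"]]))
  cat(sprintf(" independent test: AUC %.4f (95%% CI [%.4f, %.4f]), ",
              x$test$auc, x$test$ci_low, x$test$ci_high))
  cat(sprintf("sens %.4f, spec %.4f, acc %.4f\n", x$test$sensitivity,
              x$test$specificity, x$test$accuracy))
  invisible(x)
}
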