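# cases: 10 subjects with g=2, 10 with g=1 -> 30 minor / 10 major alleles
# controls: 20 subjects with g=1          -> 20 minor / 20 major alleles
toy_geno <- c(rep(2, 10), rep(1, 10), rep(1, 20))
toy_pheno <- c(rep(1, 20), rep(0, 20))

test_that("the allelic test reproduces the hand-computed 2x2 table", {
  r <- allelic_assoc(toy_geno, toy_pheno)
  expect_equal(r$chi2, 16 / 3, tolerance = 1e-9)
  expect_equal(r$odds_ratio, 3.0, tolerance = 1e-9)
  expect_equal(r$p, pchisq(16 / 3, 1, lower.tail = FALSE))

  # identical allele frequencies -> no association
  g0 <- c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 5))
  y0 <- c(rep(1, 10), rep(0, 10))
  r0 <- allelic_assoc(g0, y0)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$odds_ratio, 1)

  # zero cell -> missing odds ratio, never infinity
  rz <- allelic_assoc(c(rep(0, 10), rep(1, 10)), c(rep(1, 10), rep(0, 10)))
  expect_true(is.na(rz$odds_ratio))
  expect_error(assoc_table(matrix(3, 4, 1), c(0, 0, 1, 1)), "0/1/2")
})

test_that("p-values match an independent 1-df chi-square evaluation", {
  set.seed(51)
  for (rep in 1:20) {
    g <- rbinom(60, 2, runif(1, 0.2, 0.5))
    y <- c(0, 1, rbinom(58, 1, 0.5))
    r <- allelic_assoc(g, y)
    # for 1 df: P(X > x) = 2 * (1 - Phi(sqrt(x)))
    expect_equal(r$p, 2 * pnorm(sqrt(r$chi2), lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("the test is invariant to label swaps with reciprocal OR", {
  r <- allelic_assoc(toy_geno, toy_pheno)
  flip_allele <- allelic_assoc(2 - toy_geno, toy_pheno)
  expect_equal(flip_allele$chi2, r$chi2, tolerance = 1e-12)
  expect_equal(flip_allele$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-12)
  flip_case <- allelic_assoc(toy_geno, 1 - toy_pheno)
  expect_equal(flip_case$chi2, r$chi2, tolerance = 1e-12)
  expect_equal(flip_case$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-12)
  expect_equal(r$r_squared, flip_case$r_squared, tolerance = 1e-12)
})

test_that("ranking is stable, order-invariant and projection-consistent", {
  d <- gen_genotypes(600, 80, 3, 1.2, seed = 12)
  rk <- rank_snps(d$G, d$y)
  expect_setequal(rk, 1:80)

  # permuted SNP columns give the same identity set of top SNPs
  perm <- sample(80)
  rk_perm <- rank_snps(d$G[, perm], d$y)
  expect_setequal(perm[rk_perm[1:10]], rk[1:10])

  # restriction to a subset preserves relative order
  subset <- sort(sample(80, 30))
  rk_sub <- rank_snps(d$G[, subset], d$y)
  expect_identical(subset[rk_sub],
                   rk[rk %in% subset])

  # a huge-effect causal SNP ranks first
  dd <- gen_genotypes(1500, 50, 1, 3.0, seed = 13)
  expect_equal(rank_snps(dd$G, dd$y)[1], dd$causal)
})

test_that("the top-K sweep selects on the test set and flags the bias", {
  d <- gen_genotypes(900, 60, 5, 0.8, seed = 14)
  train <- list(G = d$G[1:600, ], y = d$y[1:600])
  test <- list(G = d$G[601:900, ], y = d$y[601:900])

  sw1 <- sweep_k(train, test, k_grid = 60, learner = "logistic")
  expect_equal(sw1$best_k, 60)

  sw <- sweep_k(train, test, k_grid = c(5, 10, 20), learner = "logistic")
  expect_equal(sw$results$k, c(5, 10, 20))
  expect_match(sw$caveat, "bias")
  expect_warning(sweep_k(train, test, k_grid = c(10, 999),
                         learner = "logistic"), "dropping")

  # null genotypes: test AUCs scatter around 1/2
  dn <- gen_genotypes(900, 60, 0, 0, seed = 15)
  trn <- list(G = dn$G[1:600, ], y = dn$y[1:600])
  ten <- list(G = dn$G[601:900, ], y = dn$y[601:900])
  swn <- sweep_k(trn, ten, k_grid = c(5, 10, 20, 40), learner = "logistic")
  n1 <- sum(ten$y == 1); n0 <- sum(ten$y == 0)
  null_sd <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(mean(swn$results$auc) - 0.5), 3 * null_sd)
})

test_that("the final report nails a perfectly informative SNP", {
  set.seed(16)
  g <- rbinom(1200, 2, 0.3)
  y <- as.numeric(g >= 1)          # deterministic in dosage
  noise <- matrix(rbinom(1200 * 9, 2, 0.3), 1200, 9)
  G <- cbind(g, noise)
  colnames(G) <- paste0("s", 1:10)
  train <- list(G = G[1:800, ], y = y[1:800])
  test <- list(G = G[801:1200, ], y = y[801:1200])
  rep1 <- gwas_report(train, test, k = 1, learner = "logistic", k_cv = 5)
  # theoretical AUC of the dosage score itself, by pair counting
  theo <- roc_auc(test$G[, rep1$snps[1]], test$y)
  expect_equal(rep1$test$auc, theo, tolerance = 0.02)
  expect_true(rep1$cv_ci[["low"]] <= rep1$cv$mean[["auc"]])

  # deterministic given seeds
  rep2 <- gwas_report(train, test, k = 1, learner = "logistic", k_cv = 5)
  expect_identical(rep1$test$auc, rep2$test$auc)
  expect_identical(rep1$cv$folds, rep2$cv$folds)

  # label permutation drives the test AUC to chance
  set.seed(17)
  yperm <- sample(test$y)
  n1 <- sum(yperm == 1); n0 <- sum(yperm == 0)
  null_sd <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  model <- rbforest:::fit_logistic_learner(
    train$G[, rep1$snps, drop = FALSE], train$y)
  perm_auc <- roc_auc(rbforest:::predict_logistic_learner(
    model, test$G[, rep1$snps, drop = FALSE]), yperm)
  expect_lt(abs(perm_auc - 0.5), 3 * null_sd)
})
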