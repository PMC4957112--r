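#' Hill/valley time-series classification task
#'
#' Each sample is a length-`length` series: a flat baseline `b ~ U(0, 10)`
#' plus a Gaussian bump `a * exp(-(t - c)^2 / (2 w^2))` with amplitude
#' `a ~ U(1, 5)`, center `c ~ U(0.2 L, 0.8 L)`, width `w ~ U(5, 15)`, added
#' (hill, y = 1) or subtracted (valley, y = 0), with N(0, `noise_sd`) noise
#' per time point. Classes are balanced to within one sample. Telling hill
#' from valley requires comparing the bump region to the (random-level)
#' baseline, which no single-feature threshold can do — a depth task.
#'
#' @param n number of samples.
#' @param length series length L (>= 10).
#' @param noise_sd per-point Gaussian noise sd.
#' @param seed integer seed; output is a pure function of the arguments.
#' @return list with `X` (n x length matrix) and `y` (0/1 vector).
#' @export
gen_hill_valley <- function(n, length = 100, noise_sd = 0.5, seed = 1) {
  stopifnot(length >= 10, n >= 2)
  withr::with_seed(as.integer(seed), {
    y <- sample(rep(c(0, 1), length.out = n))
    b <- runif(n, 0, 10)
    a <- runif(n, 1, 5)
    ctr <- runif(n, 0.2 * length, 0.8 * length)
    w <- runif(n, 5, 15)
    t_grid <- seq_len(length)
    bump <- a * exp(-(outer(ctr, t_grid, "-"))^2 / (2 * w^2))
    X <- b + ifelse(y == 1, 1, -1) * bump +
      matrix(rnorm(n * length, 0, noise_sd), n, length)
    colnames(X) <- paste0("t", t_grid)
    list(X = X, y = y)
  })
}

#' Oblique (non-axis-parallel) decision boundary task
#'
#' Standard-normal features with label `y = 1[w . x > 0]` for a fixed random
#' unit vector `w`, optionally flipped with probability `margin_noise`. The
#' Bayes boundary is a hyperplane in general position, the regime where
#' axis-parallel splits are systematically wasteful.
#'
#' @param n number of samples.
#' @param d feature dimension.
#' @param margin_noise label flip probability.
#' @param seed integer seed.
#' @return list with `X` (n x d), `y` (0/1) and the unit normal `w`.
#' @export
gen_oblique <- function(n, d, margin_noise = 0, seed = 1) {
  stopifnot(n >= 2, d >= 2, margin_noise >= 0, margin_noise < 0.5)
  withr::with_seed(as.integer(seed), {
    w <- rnorm(d)
    w <- w / sqrt(sum(w^2))
    X <- matrix(rnorm(n * d), n, d)
    y <- as.numeric(drop(X %*% w) > 0)
    flip <- runif(n) < margin_noise
    y[flip] <- 1 - y[flip]
    colnames(X) <- paste0("x", seq_len(d))
    list(X = X, y = y, w = w)
  })
}

#' Smooth nonlinear regression surface
#'
#' `y = sin(4 pi x1) * cos(4 pi x2) + 0.5 x1 + e`, `x` uniform on the unit
#' square, `e ~ N(0, noise_sd)` — a shallow task (low-dimensional, smooth)
#' in contrast to [gen_hill_valley()].
#'
#' @param n number of samples.
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `X` (n x 2) and `y`.
#' @export
gen_surface <- function(n, noise_sd = 0, seed = 1) {
  stopifnot(n >= 2)
  withr::with_seed(as.integer(seed), {
    X <- cbind(x1 = runif(n), x2 = runif(n))
    y <- sin(4 * pi * X[, 1]) * cos(4 * pi * X[, 2]) + 0.5 * X[, 1] +
      rnorm(n, 0, noise_sd)
    list(X = X, y = y)
  })
}

#' Biallelic genotypes with an additive liability disease model
#'
#' Per-SNP minor allele frequencies are uniform on `maf_range`; genotypes
#' are Binomial(2, maf) counts (Hardy-Weinberg). A random subset of
#' `n_causal` SNPs carries an additive log-odds effect `beta` per (centered)
#' minor allele: `liability = intercept + sum beta * (g - 2 maf)`, and the
#' binary phenotype is Bernoulli(logistic(liability)). With `intercept = 0`
#' the cohort is balanced in expectation.
#'
#' @param n number of subjects.
#' @param m_snps number of SNPs.
#' @param n_causal number of causal SNPs (<= `m_snps`).
#' @param beta per-allele log-odds effect of each causal SNP.
#' @param maf_range minor-allele frequency range.
#' @param intercept liability intercept (disease prevalence control).
#' @param seed integer seed.
#' @return list with `G` (n x m_snps matrix in 0/1/2), `y` (0/1 phenotype),
#'   `causal` (sorted causal SNP indices), `maf` and `beta`.
#' @export
gen_genotypes <- function(n, m_snps, n_causal, beta,
                          maf_range = c(0.05, 0.5), intercept = 0,
                          seed = 1) {
  stopifnot(n >= 2, m_snps >= 1)
  if (n_causal > m_snps)
    stop("n_causal must not exceed m_snps")
  withr::with_seed(as.integer(seed), {
    maf <- runif(m_snps, maf_range[1], maf_range[2])
    G <- matrix(rbinom(n * m_snps, 2, rep(maf, each = n)), n, m_snps)
    causal <- sort(sample.int(m_snps, n_causal))
    liability <- rep(intercept, n)
    if (n_causal > 0) {
      Gc <- sweep(G[, causal, drop = FALSE], 2, 2 * maf[causal], "-")
      liability <- liability + drop(Gc %*% rep(beta, n_causal))
    }
    y <- rbinom(n, 1, stats::plogis(liability))
    colnames(G) <- sprintf("snp%04d", seq_len(m_snps))
    list(G = G, y = y, causal = causal, maf = maf, beta = beta)
  })
}
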