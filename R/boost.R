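#' Boosting configuration for the Random Bit pool
#'
#' The pool is grown by `chains` independent gradient-boosting chains of
#' `steps` steps each, giving a pool of `chains * steps` bits. At every step
#' `cands` candidate networks are drawn and the one explaining the most
#' residual variance is kept. Defaults follow the method's stated small-data
#' settings: 256 chains, 40 steps (pool 10,240 ~ "~10,000" bits) and more
#' than 100 candidates per step.
#'
#' @param chains number of independent boosting chains (B).
#' @param steps steps per chain (S); pool size is `chains * steps`.
#' @param cands candidate Random Bits drawn per step (C).
#' @param twist1,twist2 network shape, see [sample_bit_pool()].
#' @param seed integer master seed; each chain runs on its own derived
#'   substream, so chains can be computed in any order with identical
#'   results.
#' @return a `boost_config` list.
#' @export
boost_config <- function(chains = 256, steps = 40, cands = 128,
                         twist1 = 3, twist2 = 3, seed = 1) {
  stopifnot(chains >= 1, steps >= 1, cands >= 1, twist1 >= 1, twist2 >= 1)
  structure(list(chains = as.integer(chains), steps = as.integer(steps),
                 cands = as.integer(cands), twist1 = as.integer(twist1),
                 twist2 = as.integer(twist2), seed = as.numeric(seed)),
            class = "boost_config")
}

#' Residual variance explained by a binary split
#'
#' Between-group sum of squares of `residual` split by `bits`:
#' `n0*(m0 - m)^2 + n1*(m1 - m)^2` with `m` the grand mean and `m0`, `m1`
#' the group means. Returns 0 when either group is empty (a bit constant on
#' the sample explains nothing).
#'
#' @param residual numeric vector.
#' @param bits binary 0/1 vector of the same length.
#' @return nonnegative scalar.
#' @examples
#' explained_variance(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 4
#' @export
explained_variance <- function(residual, bits) {
  if (length(residual) == 0) stop("residual must be nonempty")
  if (length(bits) != length(residual))
    stop("residual and bits must have the same length")
  one <- bits == 1
  n1 <- sum(one)
  n0 <- length(bits) - n1
  if (n0 == 0 || n1 == 0) return(0)
  s1 <- sum(residual[one])
  s0 <- sum(residual) - s1
  m0 <- s0 / n0
  m1 <- s1 / n1
  gm <- (s0 + s1) / length(residual)
  n0 * (m0 - gm) * (m0 - gm) + n1 * (m1 - gm) * (m1 - gm)
}

#' Run one gradient-boosting chain
#'
#' The residual starts at `y_work` and is updated every step: the best of
#' `cfg$cands` freshly drawn candidate networks (strict max of
#' [explained_variance()] on the current residual, first encountered wins
#' ties) is kept, and the groupwise residual means are subtracted
#' (`residual <- residual - mean[bit]`). If no candidate separates the
#' residual at all (all scores 0), the first candidate is stored so the pool
#' keeps its fixed size, and the residual is left unchanged. The chain sum
#' of squared residuals is therefore non-increasing across steps.
#'
#' @param y_work numeric working target (classification targets enter as
#'   -0.5 / +0.5, see [rbf_fit()]).
#' @param X_std standardized training matrix.
#' @param cfg a [boost_config()].
#' @param stream chain substream index (0-based); chain `b` of
#'   [build_bit_pool()] uses `stream = b - 1`.
#' @param trace if `TRUE`, record every step's full candidate bit matrix,
#'   scores and chosen index (memory-heavy; meant for small instances).
#' @return a list with `pool` (an `rbf_pool` of `cfg$steps` networks),
#'   `train_bits` (dense 0/1 matrix of the selected bits), `final_sse`, and
#'   `trace` when requested.
#' @export
run_boost_chain <- function(y_work, X_std, cfg, stream = 0, trace = FALSE) {
  stopifnot(inherits(cfg, "boost_config"))
  X_std <- as.matrix(X_std)
  storage.mode(X_std) <- "double"
  out <- cpp_run_chain(as.numeric(y_work), X_std, cfg$steps, cfg$cands,
                       cfg$twist1, cfg$twist2, cfg$seed, as.numeric(stream),
                       isTRUE(trace))
  class(out$pool) <- "rbf_pool"
  out
}

#' Build the full Random Bit feature pool
#'
#' Runs `cfg$chains` independent chains (each on its own deterministic
#' substream of `cfg$seed`) and collects their selected networks chain-major:
#' pool slot `(b - 1) * steps + s` holds chain `b`'s step-`s` bit. Training
#' bits are returned already packed.
#'
#' @inheritParams run_boost_chain
#' @return a list with `pool` (an `rbf_pool` of `chains * steps` networks),
#'   `train_bits` (a `bit_matrix` of the training-set bits) and `chain_sse`
#'   (final sum of squared residuals per chain).
#' @export
build_bit_pool <- function(y_work, X_std, cfg) {
  stopifnot(inherits(cfg, "boost_config"))
  X_std <- as.matrix(X_std)
  storage.mode(X_std) <- "double"
  out <- cpp_build_pool(as.numeric(y_work), X_std, cfg$chains, cfg$steps,
                        cfg$cands, cfg$twist1, cfg$twist2, cfg$seed)
  pool <- out$pool
  class(pool) <- "rbf_pool"
  list(pool = pool,
       train_bits = structure(
         list(n_samples = out$n_samples,
              n_bits = cfg$chains * cfg$steps,
              word_size = 64L, words = out$train_words),
         class = "bit_matrix"),
       chain_sse = out$chain_sse)
}
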