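#' Sample a pool of Random Bit networks
#'
#' A Random Bit is one binary derived feature produced by a 3-layer sparse
#' neural network with random weights: each of `twist2` hidden nodes reads
#' `twist1` distinct, uniformly chosen input features through i.i.d. standard
#' normal weights; every node (hidden and top) is a threshold unit whose
#' threshold is the node's own linear summation evaluated at one uniformly
#' drawn training sample. Both layers use a strict `>` comparison, so ties
#' (in particular the threshold sample itself) emit 0. With
#' `twist1 = 1, twist2 = 1` the network degenerates to an axis-parallel
#' single-feature split — the internal baseline the oblique features are
#' meant to beat.
#'
#' @param n_nets number of networks to draw.
#' @param X_std standardized training matrix (samples x features); needed at
#'   sampling time because thresholds are data-driven.
#' @param twist1 features wired into each hidden node (1..ncol(X_std)).
#' @param twist2 number of hidden nodes.
#' @param seed integer seed for the network sampler's own RNG stream.
#' @return an object of class `rbf_pool` holding the flat network arrays.
#' @export
sample_bit_pool <- function(n_nets, X_std, twist1 = 3, twist2 = 3, seed = 1) {
  X_std <- as.matrix(X_std)
  storage.mode(X_std) <- "double"
  pool <- cpp_sample_networks(as.integer(n_nets), X_std,
                              as.integer(twist1), as.integer(twist2),
                              as.numeric(seed))
  class(pool) <- "rbf_pool"
  pool
}

#' Evaluate a pool of Random Bit networks on data
#'
#' Deterministic given the pool: no randomness is used at evaluation time.
#'
#' @param pool an `rbf_pool`.
#' @param X_std standardized matrix with at least as many columns as the
#'   largest feature index any network uses.
#' @param packed if `TRUE` (default) return a [bit_pack()]ed `bit_matrix`,
#'   otherwise a dense 0/1 integer matrix (samples x networks).
#' @return a `bit_matrix` or integer matrix of emitted bits.
#' @export
evaluate_bit_pool <- function(pool, X_std, packed = TRUE) {
  stopifnot(inherits(pool, "rbf_pool"))
  X_std <- as.matrix(X_std)
  storage.mode(X_std) <- "double"
  if (packed) {
    structure(
      list(n_samples = nrow(X_std), n_bits = length(pool$thr_top),
           word_size = 64L,
           words = cpp_evaluate_bits_packed(unclass(pool), X_std)),
      class = "bit_matrix"
    )
  } else {
    cpp_evaluate_bits(unclass(pool), X_std)
  }
}

#' Extract one network from a pool
#'
#' Returns the per-node structure (feature indices, weights, thresholds) of
#' network `j`, mainly for inspection and testing.
#'
#' @param pool an `rbf_pool`.
#' @param j network index (1-based).
#' @return a list with one entry per hidden node plus the top layer.
#' @export
pool_network <- function(pool, j) {
  stopifnot(inherits(pool, "rbf_pool"))
  t1 <- pool$twist1
  t2 <- pool$twist2
  hidden <- lapply(seq_len(t2), function(k) {
    rows <- ((k - 1) * t1 + 1):(k * t1)
    list(feature_indices = pool$feat[rows, j] + 1L,
         weights = pool$w_hidden[rows, j],
         threshold = pool$thr_hidden[k, j])
  })
  list(hidden = hidden, top_weights = pool$w_top[, j],
       top_threshold = pool$thr_top[j], twist1 = t1, twist2 = t2)
}

#' Number of networks in a pool
#' @param pool an `rbf_pool`.
#' @return integer count.
#' @export
pool_size <- function(pool) length(pool$thr_top)

#' @export
print.rbf_pool <- function(x, ...) {
  cat(sprintf("<rbf_pool: %d networks, twist1 = %d, twist2 = %d>\n",
              pool_size(x), x$twist1, x$twist2))
  invisible(x)
}
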