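#' Forest configuration for the packed-bit random forest
#'
#' Each tree is grown on a bootstrapped sample (`sample_fraction * n` draws
#' with replacement) and a bootstrap (with replacement) of `bits_per_tree`
#' pool bits; duplicates collapse to the unique set, and every split scans
#' that whole set for the best bit. Lowering `sample_fraction` regularizes
#' small datasets by decorrelating the (then individually biased) trees.
#'
#' @param n_trees number of trees.
#' @param bits_per_tree bit bootstrap draws per tree; default
#'   `ceiling(sqrt(pool_size)) * 8`, resolved at fit time when `NULL`.
#' @param sample_fraction fraction of `n` drawn (with replacement) per tree.
#' @param min_node_size nodes smaller than `2 * min_node_size` become
#'   leaves; default 1 for classification, 5 for regression (resolved at fit
#'   time when `NULL`).
#' @param task `"regression"` (variance-reduction splits) or
#'   `"classification"` (Gini splits, leaves hold class-1 fractions).
#' @param seed integer master seed; tree `t` draws from substream `t - 1`.
#' @return a `forest_config` list.
#' @export
forest_config <- function(n_trees = 500, bits_per_tree = NULL,
                          sample_fraction = 1,
                          min_node_size = NULL,
                          task = c("regression", "classification"),
                          seed = 1) {
  task <- match.arg(task)
  stopifnot(n_trees >= 1, sample_fraction > 0, sample_fraction <= 1)
  if (!is.null(bits_per_tree)) stopifnot(bits_per_tree >= 1)
  if (!is.null(min_node_size)) stopifnot(min_node_size >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 bits_per_tree = if (is.null(bits_per_tree)) NULL
                                 else as.integer(bits_per_tree),
                 sample_fraction = as.numeric(sample_fraction),
                 min_node_size = if (is.null(min_node_size)) NULL
                                 else as.integer(min_node_size),
                 task = task, seed = as.numeric(seed)),
            class = "forest_config")
}

task_code <- function(task) if (identical(task, "classification")) 1L else 0L

resolve_forest_config <- function(cfg, n_bits) {
  if (is.null(cfg$bits_per_tree))
    cfg$bits_per_tree <- as.integer(ceiling(sqrt(n_bits)) * 8)
  cfg$bits_per_tree <- min(cfg$bits_per_tree, max(n_bits * 4L, 1L))
  if (is.null(cfg$min_node_size))
    cfg$min_node_size <- if (cfg$task == "classification") 1L else 5L
  cfg
}

#' Best bit split of a node
#'
#' Scans `cand_bits` (ascending, strict improvement, so the lowest index
#' wins ties) for the bit maximizing the impurity decrease on
#' `node_idx` — between-group sum of squares for regression, Gini decrease
#' for classification — computed through the packed grouped sums. Returns
#' bit `NA` when no candidate separates the node or no decrease is positive.
#'
#' @param bits a `bit_matrix`.
#' @param targets numeric vector of length `n_samples` (0/1 for
#'   classification).
#' @param node_idx node membership (1-based, repeats allowed).
#' @param cand_bits candidate bit indices (1-based).
#' @param task `"regression"` or `"classification"`.
#' @return list with `bit` (1-based or `NA`) and `score`.
#' @export
best_bit_split <- function(bits, targets, node_idx, cand_bits, task) {
  stopifnot(inherits(bits, "bit_matrix"))
  r <- cpp_best_split(bits$words, bits$n_samples, bits$n_bits,
                      as.numeric(targets), as.integer(node_idx) - 1L,
                      as.integer(sort(unique(cand_bits))) - 1L,
                      task_code(task))
  list(bit = if (r$bit < 0) NA_integer_ else r$bit + 1L, score = r$score)
}

#' Fit the packed-bit random forest
#'
#' @param bits a `bit_matrix` of training bits (from [build_bit_pool()] or
#'   [evaluate_bit_pool()]).
#' @param targets numeric targets (0/1 for classification).
#' @param cfg a [forest_config()].
#' @return an object of class `bit_forest`.
#' @export
fit_bit_forest <- function(bits, targets, cfg) {
  stopifnot(inherits(bits, "bit_matrix"), inherits(cfg, "forest_config"))
  n <- bits$n_samples
  if (length(targets) != n) stop("targets must have length n_samples")
  if (bits$n_bits < 1) stop("cannot grow a forest on an empty bit pool")
  cfg <- resolve_forest_config(cfg, bits$n_bits)
  n_draw <- max(1L, as.integer(floor(cfg$sample_fraction * n)))
  tcode <- task_code(cfg$task)
  trees <- vector("list", cfg$n_trees)
  for (t in seq_len(cfg$n_trees)) {
    d <- cpp_forest_draws(cfg$seed, t - 1L, n, n_draw, bits$n_bits,
                          cfg$bits_per_tree)
    uniq <- sort(unique(d$bit_idx))
    trees[[t]] <- cpp_grow_tree(bits$words, n, bits$n_bits,
                                as.numeric(targets), d$sample_idx, uniq,
                                cfg$min_node_size, tcode)
  }
  structure(list(trees = trees, config = cfg, n_bits = bits$n_bits),
            class = "bit_forest")
}

#' Predict from a packed-bit forest
#'
#' The prediction is the mean of the tree leaf values: a real value for
#' regression, a class-1 probability in \[0, 1\] for classification.
#'
#' @param object a `bit_forest`.
#' @param bits a `bit_matrix` of the new samples' bits, computed from the
#'   same pool networks the forest was trained on.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.bit_forest <- function(object, bits, ...) {
  stopifnot(inherits(bits, "bit_matrix"))
  if (bits$n_bits != object$n_bits)
    stop("bit matrix has ", bits$n_bits, " bits but the forest was grown ",
         "on a pool of ", object$n_bits)
  cpp_predict_forest(object$trees, bits$words, bits$n_samples, bits$n_bits)
}

#' @export
print.bit_forest <- function(x, ...) {
  cat(sprintf("<bit_forest: %d trees, %s, pool of %d bits>\n",
              length(x$trees), x$config$task, x$n_bits))
  invisible(x)
}
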