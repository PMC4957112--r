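#' Pack binary feature columns into a bit matrix
#'
#' Stores binary features in a compressed column-major layout using one bit
#' per sample per feature: 64-bit words, least-significant bit = lowest
#' sample index, padding bits past `n_samples` zeroed. The packed matrix is
#' immutable and is shared by all trees of a [fit_bit_forest()] ensemble;
#' bootstrap multiplicity is carried by index subsets, never by the matrix.
#'
#' @param x a list of binary (0/1) vectors of equal length, or a numeric
#'   matrix with one feature per column.
#' @param n_samples required when `x` has zero columns, otherwise inferred.
#' @return an object of class `bit_matrix` with fields `n_samples`,
#'   `n_bits`, `word_size` (always 64) and the packed `words` (raw vector).
#' @examples
#' bm <- bit_pack(list(c(1, 0, 1, 1, 0, 0, 0, 1)))
#' bit_popcount(bm, 1)  # 4
#' @export
bit_pack <- function(x, n_samples = NULL) {
  if (is.list(x)) {
    if (length(x) == 0) {
      if (is.null(n_samples))
        stop("n_samples must be given when packing zero columns")
      mat <- matrix(0L, nrow = n_samples, ncol = 0L)
    } else {
      lens <- lengths(x)
      if (length(unique(lens)) != 1L)
        stop("all bit columns must have the same length")
      mat <- matrix(as.integer(unlist(x)), nrow = lens[[1]])
    }
  } else if (is.matrix(x)) {
    mat <- x
    storage.mode(mat) <- "integer"
  } else {
    stop("x must be a list of binary vectors or a matrix")
  }
  if (anyNA(mat)) stop("bit entries must be 0 or 1, not NA")
  structure(
    list(n_samples = nrow(mat), n_bits = ncol(mat), word_size = 64L,
         words = cpp_pack(mat)),
    class = "bit_matrix"
  )
}

#' Unpack a bit matrix into a dense 0/1 matrix
#'
#' Inverse of [bit_pack()]: `bit_unpack(bit_pack(x))` reproduces `x`.
#'
#' @param bm a `bit_matrix`.
#' @return an integer matrix of 0s and 1s, `n_samples` x `n_bits`.
#' @export
bit_unpack <- function(bm) {
  stopifnot(inherits(bm, "bit_matrix"))
  cpp_unpack(bm$words, bm$n_samples, bm$n_bits)
}

#' Population count of one packed bit column
#'
#' @param bm a `bit_matrix`.
#' @param j column index (1-based).
#' @return the number of set bits in column `j`.
#' @export
bit_popcount <- function(bm, j) {
  stopifnot(inherits(bm, "bit_matrix"))
  cpp_popcount_col(bm$words, bm$n_samples, bm$n_bits, as.integer(j) - 1L)
}

#' Grouped counts and sums split by a stored bit
#'
#' For a subset of sample indices (repeats allowed, so bootstrap multisets
#' work unchanged), splits `values` by the stored bit of column `j` and
#' returns the group sizes and sums. This is the primitive behind both the
#' boosting variance scan and the forest split search.
#'
#' @param bm a `bit_matrix`.
#' @param j column index (1-based).
#' @param values numeric vector of length `n_samples`.
#' @param subset sample indices (1-based, repeats allowed); defaults to all
#'   samples once.
#' @return a named list with `n0`, `sum0`, `n1`, `sum1`.
#' @export
bit_group_sums <- function(bm, j, values, subset = seq_len(bm$n_samples)) {
  stopifnot(inherits(bm, "bit_matrix"))
  r <- cpp_group_sums(bm$words, bm$n_samples, bm$n_bits,
                      as.integer(j) - 1L, as.numeric(values),
                      as.integer(subset) - 1L)
  list(n0 = r[[1]], sum0 = r[[2]], n1 = r[[3]], sum1 = r[[4]])
}

#' @export
print.bit_matrix <- function(x, ...) {
  cat(sprintf("<bit_matrix: %d samples x %d bits, %d-bit words, %.1f KB>\n",
              x$n_samples, x$n_bits, x$word_size,
              length(x$words) / 1024))
  invisible(x)
}
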