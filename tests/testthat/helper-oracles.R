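# Independent naive reference implementations. These deliberately avoid the
# packed representation and the compiled code paths; where a test asserts
# bit-for-bit equality the oracle mirrors the documented arithmetic order
# (sequential double accumulation, ascending candidate scan, strict ">").

# sequential double accumulation (R's sum() uses extended precision)
seq_sum <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s
}

naive_group_sums <- function(bits_col, values, subset) {
  n0 <- 0; s0 <- 0; n1 <- 0; s1 <- 0
  for (i in subset) {
    if (bits_col[i] == 1) { n1 <- n1 + 1; s1 <- s1 + values[i] }
    else                  { n0 <- n0 + 1; s0 <- s0 + values[i] }
  }
  list(n0 = n0, sum0 = s0, n1 = n1, sum1 = s1)
}

# straight-loop evaluation of one network from pool_network()
naive_eval_network <- function(net, X_std) {
  n <- nrow(X_std)
  s <- rep(0, n)
  for (k in seq_along(net$hidden)) {
    nd <- net$hidden[[k]]
    z <- rep(0, n)
    for (j in seq_along(nd$feature_indices))
      z <- z + nd$weights[j] * X_std[, nd$feature_indices[j]]
    h <- as.numeric(z > nd$threshold)
    s <- s + net$top_weights[k] * h
  }
  as.integer(s > net$top_threshold)
}

# exhaustive split scoring on a dense 0/1 matrix; cand is 1-based ascending,
# returned bit is 0-based (-1 = none) to match the compiled trees
naive_best_split <- function(bits_mat, targets, idx, cand, task) {
  nt <- length(idx)
  st <- seq_sum(targets[idx])
  best_bit <- -1L
  best_score <- 0
  for (j in cand) {
    b <- bits_mat[idx, j]
    n1 <- sum(b == 1)
    n0 <- nt - n1
    if (n0 == 0 || n1 == 0) next
    s1 <- seq_sum(targets[idx][b == 1])
    s0 <- st - s1
    if (task == "regression") {
      m0 <- s0 / n0; m1 <- s1 / n1; gm <- st / nt
      score <- n0 * (m0 - gm) * (m0 - gm) + n1 * (m1 - gm) * (m1 - gm)
    } else {
      p <- st / nt; p0 <- s0 / n0; p1 <- s1 / n1
      gp <- 2 * p * (1 - p)
      score <- gp - (n0 * (2 * p0 * (1 - p0)) +
                     n1 * (2 * p1 * (1 - p1))) / nt
    }
    if (score > best_score) { best_score <- score; best_bit <- j - 1L }
  }
  list(bit = best_bit, score = best_score)
}

# plain recursive tree builder on the dense matrix; same node layout
# (preorder, left = bit 0 first) and stopping rules as the packed builder
naive_grow_tree <- function(bits_mat, targets, sample_idx, cand, min_node,
                            task) {
  sb <- integer(0); lf <- integer(0); rt <- integer(0); vl <- numeric(0)
  grow <- function(idx) {
    nt <- length(idx)
    st <- seq_sum(targets[idx])
    me <- length(sb)
    sb <<- c(sb, -1L); lf <<- c(lf, -1L); rt <<- c(rt, -1L)
    vl <<- c(vl, st / nt)
    if (all(targets[idx] == targets[idx][1]) || nt < 2 * min_node)
      return(me)
    bs <- naive_best_split(bits_mat, targets, idx, cand, task)
    if (bs$bit < 0) return(me)
    sb[me + 1] <<- bs$bit
    b <- bits_mat[idx, bs$bit + 1]
    l <- grow(idx[b == 0])
    r <- grow(idx[b == 1])
    lf[me + 1] <<- l
    rt[me + 1] <<- r
    me
  }
  grow(sample_idx)
  list(split_bit = sb, left = lf, right = rt, value = vl)
}

naive_predict_tree <- function(tree, bits_mat) {
  vapply(seq_len(nrow(bits_mat)), function(i) {
    node <- 1L
    while (tree$split_bit[node] >= 0) {
      node <- if (bits_mat[i, tree$split_bit[node] + 1] == 1)
        tree$right[node] + 1L else tree$left[node] + 1L
    }
    tree$value[node]
  }, numeric(1))
}

# AUC by explicit positive-negative pair counting, ties worth 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# exact signed-rank null: enumerate all 2^n sign assignments
exact_wilcoxon_p <- function(x, y, alternative) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- drop(signs %*% r)
  switch(alternative,
         less = mean(ws <= w_obs),
         greater = mean(ws >= w_obs),
         two_sided = min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))))
}

# fit a tiny deterministic model quickly (for CV plumbing tests)
mean_fit <- function(X, y) mean(y)
mean_predict <- function(model, X) rep(model, nrow(X))
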