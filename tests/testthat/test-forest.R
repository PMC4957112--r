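test_that("best split prefers the perfect separator and handles no-split", {
  bm <- bit_pack(list(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  y <- c(0, 0, 1, 1)
  s <- best_bit_split(bm, y, 1:4, 1:2, task = "classification")
  expect_equal(s$bit, 1L)
  expect_equal(s$score, 0.5)

  # constant candidates on the node -> no split
  const <- bit_pack(list(c(1, 1, 1, 1), c(0, 0, 0, 0)))
  s2 <- best_bit_split(const, y, 1:4, 1:2, task = "classification")
  expect_true(is.na(s2$bit))
})

test_that("best split agrees with exhaustive naive scoring", {
  set.seed(5)
  for (rep in 1:30) {
    n <- 300
    k <- 50
    mat <- matrix(rbinom(n * k, 1, runif(1, 0.2, 0.8)), n, k)
    bm <- bit_pack(mat)
    task <- if (rep %% 2 == 0) "regression" else "classification"
    y <- if (task == "regression") rnorm(n) else rbinom(n, 1, 0.5)
    node <- sample(n, sample(10:n, 1), replace = TRUE)
    got <- best_bit_split(bm, y, node, 1:k, task)
    want <- naive_best_split(mat, y, node, 1:k, task)
    expect_equal(if (is.na(got$bit)) -1L else got$bit - 1L, want$bit)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("tree growth obeys the stopping rules", {
  # one perfectly separating bit -> depth-1 tree with pure leaves
  mat <- matrix(c(0, 0, 1, 1), 4, 1)
  bm <- bit_pack(mat)
  y <- c(0, 0, 1, 1)
  tree <- rbforest:::cpp_grow_tree(bm$words, 4L, 1L, as.numeric(y),
                                   0:3, 0L, 1L, 1L)
  expect_equal(tree$split_bit, c(0L, -1L, -1L))
  expect_equal(tree$value[tree$left[1] + 1], 0)
  expect_equal(tree$value[tree$right[1] + 1], 1)

  # min_node_size >= n -> a single leaf at the bootstrap mean
  y2 <- c(1, 2, 3, 4)
  idx <- c(0L, 0L, 2L, 3L)
  leaf <- rbforest:::cpp_grow_tree(bm$words, 4L, 1L, y2, idx, 0L, 10L, 0L)
  expect_equal(leaf$split_bit, -1L)
  expect_equal(leaf$value, mean(y2[idx + 1]))
})

test_that("packed trees equal a naive unpacked builder given shared draws", {
  set.seed(6)
  for (rep in 1:8) {
    n <- sample(80:250, 1)
    k <- sample(10:50, 1)
    mat <- matrix(rbinom(n * k, 1, 0.5), n, k)
    bm <- bit_pack(mat)
    task <- if (rep %% 2 == 0) "regression" else "classification"
    y <- if (task == "regression") rnorm(n) else rbinom(n, 1, 0.5)
    cfg <- forest_config(n_trees = 2, bits_per_tree = k, min_node_size = 2,
                         sample_fraction = 0.8, task = task, seed = rep)
    forest <- fit_bit_forest(bm, y, cfg)
    n_draw <- floor(0.8 * n)
    for (t in 1:2) {
      d <- rbforest:::cpp_forest_draws(cfg$seed, t - 1L, n, n_draw, k, k)
      ref <- naive_grow_tree(mat, y, d$sample_idx + 1L,
                             sort(unique(d$bit_idx)) + 1L, 2, task)
      expect_identical(forest$trees[[t]]$split_bit, ref$split_bit)
      expect_identical(forest$trees[[t]]$left, ref$left)
      expect_identical(forest$trees[[t]]$right, ref$right)
      expect_equal(forest$trees[[t]]$value, ref$value, tolerance = 1e-14)
    }
  }
})

test_that("forest predictions are convex averages of leaf values", {
  # hand-built single-leaf trees average to the leaf constant
  leaf <- list(split_bit = -1L, left = -1L, right = -1L, value = 0.7)
  bm <- bit_pack(matrix(rbinom(20, 1, 0.5), 10, 2))
  pred <- rbforest:::cpp_predict_forest(list(leaf, leaf, leaf), bm$words,
                                        10L, 2L)
  expect_equal(pred, rep(0.7, 10))

  # fitted regression forest stays within the target range
  set.seed(8)
  mat <- matrix(rbinom(200 * 30, 1, 0.5), 200, 30)
  bmr <- bit_pack(mat)
  y <- rnorm(200, 10, 3)
  f <- fit_bit_forest(bmr, y, forest_config(n_trees = 30, task = "regression",
                                            seed = 2))
  p <- predict(f, bmr)
  expect_true(all(p >= min(y) & p <= max(y)))

  # classification probabilities live in [0, 1]
  yc <- rbinom(200, 1, 0.4)
  fc <- fit_bit_forest(bmr, yc, forest_config(n_trees = 30,
                                              task = "classification",
                                              seed = 3))
  pc <- predict(fc, bmr)
  expect_true(all(pc >= 0 & pc <= 1))

  # pool-size mismatch is a model-consistency error
  wrong <- bit_pack(matrix(rbinom(200 * 5, 1, 0.5), 200, 5))
  expect_error(predict(f, wrong), "pool")
})

test_that("averaging trees reduces training error on a two-cluster task", {
  wins <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 200
    y <- rbinom(n, 1, 0.5)
    X <- scale(matrix(rnorm(n * 4), n, 4) + 1.2 * y)
    pool <- sample_bit_pool(64, X, seed = s)
    bits <- evaluate_bit_pool(pool, X)
    cfg1 <- forest_config(n_trees = 1, sample_fraction = 0.6,
                          task = "classification", seed = s)
    cfgM <- forest_config(n_trees = 100, sample_fraction = 0.6,
                          task = "classification", seed = s)
    e1 <- mean((predict(fit_bit_forest(bits, y, cfg1), bits) - y)^2)
    eM <- mean((predict(fit_bit_forest(bits, y, cfgM), bits) - y)^2)
    if (eM <= e1) wins <- wins + 1
  }
  expect_gte(wins, 18)
})
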