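#' Fit a feature scaler
#'
#' Columnwise standardization: subtract the mean, divide by the sample
#' (n - 1) standard deviation. Zero-variance columns keep sd = 1 so they map
#' to an all-zero standardized column, which no hidden node can use
#' informatively but which never breaks a fit.
#'
#' @param X numeric matrix or data frame (samples x features).
#' @return an object of class `feature_scaler`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  structure(list(means = m, sds = s), class = "feature_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler a [fit_scaler()] result.
#' @param X matrix with the same number of columns as the training data.
#' @return the standardized matrix.
#' @export
scale_features <- function(scaler, X) {
  stopifnot(inherits(scaler, "feature_scaler"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != length(scaler$means))
    stop("X has ", ncol(X), " columns but the scaler was fit on ",
         length(scaler$means))
  sweep(sweep(X, 2, scaler$means, "-"), 2, scaler$sds, "/")
}

RBF_FORMAT_VERSION <- 1L

resolve_task <- function(task, y) {
  if (!is.null(task) && task != "auto") return(task)
  if (is.factor(y) || is.character(y) || is.logical(y)) "classification"
  else "regression"
}

encode_target <- function(y, task) {
  if (task == "regression") {
    y <- as.numeric(y)
    if (anyNA(y)) stop("y contains missing values")
    return(list(y01 = y, levels = NULL))
  }
  if (is.factor(y) || is.character(y)) {
    f <- factor(y)
    if (nlevels(f) != 2)
      stop("only binary classification is supported (got ",
           nlevels(f), " classes)")
    list(y01 = as.numeric(f) - 1, levels = levels(f))
  } else {
    y <- as.numeric(y)
    if (anyNA(y)) stop("y contains missing values")
    u <- sort(unique(y))
    if (!all(u %in% c(0, 1)) || length(u) > 2)
      stop("classification target must be binary (0/1 or a 2-level factor)")
    list(y01 = y, levels = NULL)
  }
}

#' Fit a Random Bits Forest
#'
#' The full pipeline: standardize the features, grow the Random Bit pool by
#' multi-chain gradient boosting ([build_bit_pool()]), pack the training
#' bits, and fit the packed-bit random forest ([fit_bit_forest()]).
#' Classification targets enter the (purely least-squares) boosting recoded
#' to -0.5/+0.5 so the first grand-mean subtraction is symmetric; class
#' probabilities come from the forest, never from the boosting.
#'
#' Everything is reproducible from `(data, seed)`: boosting chains and trees
#' run on deterministic substreams, so refitting with the same inputs gives
#' an identical model.
#'
#' @param X feature matrix or data frame, no missing values.
#' @param y target vector: numeric for regression; 0/1, logical or a 2-level
#'   factor for classification.
#' @param task `"auto"` (factor/character/logical y means classification),
#'   `"regression"` or `"classification"`.
#' @param chains,steps,cands,twist1,twist2 pool parameters, see
#'   [boost_config()].
#' @param n_trees,bits_per_tree,sample_fraction,min_node_size forest
#'   parameters, see [forest_config()].
#' @param seed single integer seed driving both stages (on separate derived
#'   streams).
#' @return an object of class `rbf_model`.
#' @examples
#' d <- gen_oblique(300, d = 5, margin_noise = 0, seed = 1)
#' fit <- rbf_fit(d$X[1:200, ], d$y[1:200], task = "classification",
#'                chains = 8, steps = 5, cands = 32, n_trees = 50, seed = 1)
#' p <- predict(fit, d$X[201:300, ], type = "class")
#' mean(p != d$y[201:300])
#' @export
rbf_fit <- function(X, y, task = "auto", chains = 256, steps = 40,
                    cands = 128, twist1 = 3, twist2 = 3, n_trees = 500,
                    bits_per_tree = NULL, sample_fraction = 1,
                    min_node_size = NULL, seed = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("X contains missing values; impute or drop them first")
  if (nrow(X) != length(y)) stop("X and y disagree on the number of samples")
  task <- resolve_task(task, y)
  enc <- encode_target(y, task)
  y_work <- if (task == "classification") enc$y01 - 0.5 else enc$y01

  bcfg <- boost_config(chains = chains, steps = steps, cands = cands,
                       twist1 = twist1, twist2 = twist2,
                       seed = cpp_mix_seed(seed, 0))
  fcfg <- forest_config(n_trees = n_trees, bits_per_tree = bits_per_tree,
                        sample_fraction = sample_fraction,
                        min_node_size = min_node_size, task = task,
                        seed = cpp_mix_seed(seed, 1))

  scaler <- fit_scaler(X)
  X_std <- scale_features(scaler, X)
  built <- build_bit_pool(y_work, X_std, bcfg)
  forest <- fit_bit_forest(built$train_bits, enc$y01, fcfg)

  structure(list(format_version = RBF_FORMAT_VERSION,
                 scaler = scaler, pool = built$pool, forest = forest,
                 task = task, boost_cfg = bcfg,
                 forest_cfg = forest$config,
                 chain_sse = built$chain_sse,
                 n_features = ncol(X),
                 feature_names = colnames(X),
                 class_levels = enc$levels,
                 seed = as.numeric(seed)),
            class = "rbf_model")
}

#' Predict from a Random Bits Forest
#'
#' Applies the stored scaler, evaluates every pool network on the new data,
#' packs the bits and averages the tree predictions. Deterministic: no RNG
#' is consumed at prediction time.
#'
#' @param object an [rbf_fit()] model.
#' @param newdata matrix or data frame with the training feature count.
#' @param type `"response"` (regression value / class-1 probability),
#'   `"prob"` (probability, classification only) or `"class"` (thresholded
#'   at 0.5, classification only).
#' @param ... unused.
#' @return numeric vector, or the original class labels for
#'   `type = "class"`.
#' @export
predict.rbf_model <- function(object, newdata,
                              type = c("response", "prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (anyNA(newdata)) stop("newdata contains missing values")
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " columns but the model was ",
         "trained on ", object$n_features)
  X_std <- scale_features(object$scaler, newdata)
  bits <- evaluate_bit_pool(object$pool, X_std, packed = TRUE)
  pred <- predict(object$forest, bits)
  if (object$task == "regression") {
    if (type != "response")
      stop("type = \"", type, "\" is only available for classification")
    return(pred)
  }
  switch(type,
         response = pred,
         prob = pred,
         class = {
           lab <- as.integer(pred > 0.5)
           if (!is.null(object$class_levels))
             factor(object$class_levels[lab + 1L],
                    levels = object$class_levels)
           else lab
         })
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf(paste0("<rbf_model (%s): pool %d bits (B=%d, S=%d, C=%d, ",
                     "twist %d/%d), %d trees, %d features>\n"),
              x$task, pool_size(x$pool), x$boost_cfg$chains,
              x$boost_cfg$steps, x$boost_cfg$cands, x$boost_cfg$twist1,
              x$boost_cfg$twist2, length(x$forest$trees), x$n_features))
  invisible(x)
}

#' Save / load a Random Bits Forest model
#'
#' The model is written with R's native serialization (XDR, platform
#' independent) and carries an explicit `format_version`; loading validates
#' the container and the version and raises a format error on corrupted or
#' foreign files rather than mispredicting silently. `rbf_load(rbf_save(m))`
#' reproduces predictions bit-for-bit.
#'
#' @param model an `rbf_model`.
#' @param path file path.
#' @return `rbf_save` returns `path` invisibly; `rbf_load` returns the
#'   restored `rbf_model`.
#' @export
rbf_save <- function(model, path) {
  stopifnot(inherits(model, "rbf_model"))
  saveRDS(model, path, version = 3, compress = FALSE)
  invisible(path)
}

#' @rdname rbf_save
#' @export
rbf_load <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e)
    stop("not a valid rbf model file (", conditionMessage(e), ")",
         call. = FALSE))
  if (!inherits(model, "rbf_model") || is.null(model$format_version))
    stop("not a valid rbf model file (missing header)", call. = FALSE)
  if (model$format_version != RBF_FORMAT_VERSION)
    stop("model format version ", model$format_version,
         " is not supported (expected ", RBF_FORMAT_VERSION, ")",
         call. = FALSE)
  model
}
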