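#' Published RMSE comparison of RF vs Random Bits Forest
#'
#' The 14 regression-benchmark RMSE pairs (plain random forest vs Random
#' Bits Forest on public UCI datasets) bundled as the worked example for
#' [wilcoxon_paired()]: with zeros dropped, midranks, tie-corrected normal
#' approximation and continuity correction, the one-sided test of the RBF
#' column against the RF column gives p ~ 0.0072.
#'
#' @return data frame with columns `dataset`, `n`, `n_features`, `rf`,
#'   `rbf`.
#' @examples
#' b <- benchmark_rmse()
#' wilcoxon_paired(b$rbf, b$rf, alternative = "less")$p
#' @export
benchmark_rmse <- function() {
  read.csv(system.file("extdata", "regression_benchmark_rmse.csv",
                       package = "rbforest"))
}
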