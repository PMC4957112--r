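Package: rbforest
Title: Random Bits Forest for Classification and Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Random Bits Forest, an ensemble learner that derives roughly ten
    thousand binary features from small 3-layer sparse neural networks with
    random weights, selects them with independent gradient-boosting chains,
    packs them one bit per sample, and feeds them to a modified random forest
    that splits on the best packed bit. Includes the evaluation statistics
    used to benchmark such learners (RMSE, classification error, ROC/AUC with
    Hanley-McNeil confidence intervals, Youden-optimal thresholds, stratified
    k-fold cross-validation, paired Wilcoxon signed-rank comparison), seeded
    synthetic-data generators (hill/valley time series, oblique decision
    boundaries, smooth regression surfaces, Hardy-Weinberg genotypes with
    additive liability effects), and a case-control GWAS pipeline built on
    allelic association ranking and a top-K marker sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
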