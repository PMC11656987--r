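Package: ltrlearn
Title: Detection, Classification and Explainable Analysis of LTR Retrotransposon Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for studying the long terminal repeats (LTRs) of plant
    LTR retrotransposons with machine learning. Provides curated positive and
    negative sequence-set construction (redundancy clustering, solo-LTR
    screening, order-2 Markov resampling), three featurization tracks
    (PWM-based transcription-factor binding-site counts with TF-IDF weighting,
    one-hot encoding, k-mer tokenization), two trainable model tracks (a
    gradient-boosted ensemble on TFBS features and a CNN-LSTM on one-hot
    sequences) plus a windowed-embedding pooling head, stratified evaluation
    with Wilcoxon and Friedman/Nemenyi model comparison, and an explainability
    layer: Shapley-value attribution and its positional aggregations,
    perturbation importance, CNN-filter-to-motif mapping with MEME export, and
    LTR terminal tetramer analysis. A synthetic LTR-like data generator with a
    planted-signal truth table makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
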