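# ltrlearn

Machine learning for the long terminal repeats (LTRs) of plant LTR
retrotransposons — detection, superfamily/family classification, and the
explainability analyses that turn trained classifiers back into statements
about sequence biology.

LTRs are the regulatory modules of retrotransposons: a few hundred to a few
thousand bases flanked by canonical `TG..CA` termini, carrying a core
promoter (TATA box, consensus `TATAWA`) and transcription-factor binding
sites (TFBS). They are too variable for alignment-based comparison, so
`ltrlearn` treats them as a sequence-classification problem with three
tasks (LTR vs non-LTR, Ty1/Copia vs Ty3/Gypsy, 15-way family) and three
featurizations:

* **TFBS track** — PWM log-odds scanning with a range-relative occurrence
  threshold (score ≥ min + 0.8·(max − min)), TF-IDF weighting
  (`idf(t) = ln((1+N)/(1+df)) + 1`, L2 rows), gradient-boosted trees;
* **one-hot track** — a CNN-LSTM (1-D convolution → ReLU → max pooling →
  masked bidirectional LSTM → sigmoid/softmax head) written in
  RcppArmadillo with hand-derived, finite-difference-checked gradients;
* **embedding track** — 510-base windows, stride 170, average-pooled
  fixed-dimension embeddings (any embedder satisfying the contract; a
  deterministic k-mer-hash projector ships as the offline default) under a
  small convolutional head.

Around the models: CD-HIT-style greedy identity clustering, solo-LTR
screening, order-2 Markov negative-set synthesis, stratified splits and
k-fold evaluation, exact tie-aware Wilcoxon signed-rank and
Friedman/Nemenyi model comparison, TreeSHAP / permutation-Shapley /
integrated-gradients attribution with positional and k-mer aggregation,
TATA/TSS anchor-centered importance matrices, CNN-filter-to-PWM export
(`exp(λS/max S)`, λ = 3) with MEME output and an internal motif matcher,
and the 5'/3' terminal tetramer analysis with canonical `TG..CA` 1-bp shift
assignment. A synthetic LTR generator with a planted-signal truth table
makes the whole pipeline testable without downloads.

## Worked example

```r
library(ltrlearn)

ds    <- generate_dataset(synthetic_spec(n_positive = 300, n_negative = 300,
                                         length_range = c(300L, 1000L),
                                         seed = 42))
seqs  <- dplyr::bind_rows(ds$positives, ds$negatives[names(ds$positives)])
split <- split_dataset(seqs, stratify_by = "is_ltr", seed = 1)

counts   <- scan_pwm_counts(seqs, ds$motifs, rel_threshold = 0.8)
train_ft <- tfidf_transform(counts[match(split$train$id, seqs$id), ])
test_ft  <- tfidf_transform(counts[match(split$test$id, seqs$id), ],
                            idf = attr(train_ft, "idf"))

fit <- train_gbdt(train_ft, split$train$is_ltr,
                  hyperparams = list(nrounds = 150, max_depth = 3), seed = 1)
glance(compute_metrics(as.character(split$test$is_ltr),
                       predict(fit, test_ft),
                       averaging = "binary", positive = "TRUE"))
#> # A tibble: 1 × 4
#>   precision recall    f1 averaging
#>       <dbl>  <dbl> <dbl> <chr>
#> 1     0.983  0.983 0.983 binary
```

The held-out F1 of 0.98 says the TFBS features separate LTR-like positives
from composition-matched negatives almost perfectly at this scale. The
attribution layer identifies which planted motifs carried the decision:

```r
shap <- tree_shap(fit, test_ft)
head(sort(colMeans(abs(shap$values)), decreasing = TRUE), 3)
#>    CRM_m2 Alesia_m2 Angela_m2
#> 0.3081788 0.2765355 0.2104872
```

and the terminal tetramer analysis recovers the canonical edge pairs of the
two superfamilies, with their shares of the summarized counts:

```r
summarize_edges(edge_tetramers(ds$positives))
#> # A tibble: 2 × 5
#>   canonical_t5 canonical_t3 total percent complementarity
#> 1 TGTT         AACA           180      60               4
#> 2 TGAT         ATCA           120      40               4
```

`vignettes/ltr-classification-methods.Rmd` documents the models, their
assumptions, every tunable parameter, and the design decisions; a thin
command-line front end (`scripts/ltrlearn`) exposes the
synth/featurize/train/evaluate/edges pipelines for shell use.

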