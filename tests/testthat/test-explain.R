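test_that("tree SHAP is additive and equals brute-force coalition Shapley", {
  withr::with_seed(61, {
    x <- matrix(rnorm(60 * 3), 60, 3)
    colnames(x) <- c("fa", "fb", "fc")
    y <- as.numeric(x[, 1] + 0.7 * x[, 2] * (x[, 1] > 0) > 0)
    feats <- dplyr::bind_cols(tibble::tibble(seq_id = sprintf("i%02d", 1:60)),
                              tibble::as_tibble(x))
    attr(feats, "kind") <- "counts"
    fit <- train_gbdt(feats, y == 1,
                      hyperparams = list(nrounds = 10, max_depth = 3), seed = 1)
    shap <- tree_shap(fit, feats)
    # additivity: base + contributions reproduce the margin exactly
    margins <- predict(fit, feats, type = "margin")
    expect_lt(max(abs(rowSums(shap$values) + shap$base_value - margins)), 1e-5)
    # brute-force coalition equality on a handful of instances
    for (i in c(1, 7, 23)) {
      phi <- oracle_tree_shap(fit, as.list(feats[i, -1]))
      expect_equal(unname(shap$values[i, ]), unname(phi), tolerance = 1e-5)
    }
  })
})

test_that("tree SHAP gives zero attribution to unused features", {
  withr::with_seed(63, {
    x <- tibble::tibble(seq_id = sprintf("i%02d", 1:80),
                        used = c(rnorm(40, 3), rnorm(40, -3)),
                        unused = rnorm(80))
    y <- rep(c(TRUE, FALSE), each = 40)
    fit <- train_gbdt(x, y, hyperparams = list(nrounds = 5, max_depth = 1),
                      seed = 1)
    shap <- tree_shap(fit, x)
    expect_true(all(abs(shap$values[, "unused"]) < 1e-12))
    # single-feature stump: attribution equals f(x) - E[f]
    expect_lt(max(abs(shap$values[, "used"] + shap$base_value -
                        predict(fit, x, type = "margin"))), 1e-5)
  })
  err_model <- structure(list(), class = "ltr_cnn_lstm")
  expect_error(tree_shap(err_model, NULL), "tree-ensemble")
})

test_that("permutation-sampling Shapley recovers the linear closed form", {
  withr::with_seed(65, {
    p <- 4
    w <- c(2, -1, 0.5, 0)
    f <- function(m) as.matrix(m) %*% w
    bg <- matrix(rnorm(200 * p), 200, p)
    colnames(bg) <- paste0("f", 1:p)
    inst <- matrix(rnorm(3 * p), 3, p)
    colnames(inst) <- paste0("f", 1:p)
    shap <- model_agnostic_shap(f, inst, bg, n_samples = 60, seed = 2)
    for (i in 1:3) {
      closed <- w * (inst[i, ] - colMeans(bg))
      expect_lt(max(abs(shap$values[i, ] - closed)), 0.2) # MC tolerance
    }
    # additivity within Monte-Carlo tolerance
    expect_lt(max(abs(rowSums(shap$values) + shap$base_value -
                        as.numeric(f(inst)))), 0.3)
    # constant model -> all-zero attributions
    shap0 <- model_agnostic_shap(function(m) rep(2, nrow(m)), inst, bg,
                                 n_samples = 10, seed = 1)
    expect_true(all(shap0$values == 0))
    expect_error(model_agnostic_shap(f, inst, bg[0, , drop = FALSE]),
                 "non-empty")
  })
})

test_that("more permutation samples reduce attribution variance", {
  withr::with_seed(67, {
    p <- 3
    f <- function(m) as.matrix(m)[, 1] * as.matrix(m)[, 2]
    bg <- matrix(rnorm(50 * p), 50, p)
    inst <- matrix(rnorm(p), 1, p)
    est <- function(n_samples, seed) {
      model_agnostic_shap(f, inst, bg, n_samples = n_samples,
                          seed = seed)$values[1, 1]
    }
    v_small <- var(vapply(1:12, function(s) est(4, s), numeric(1)))
    v_large <- var(vapply(1:12, function(s) est(40, s), numeric(1)))
    expect_lt(v_large, v_small)
  })
})

test_that("perturbation importance isolates the decisive feature", {
  fx <- planted_motif_fixture(n_per_class = 80, L = 250, seed = 69)
  mots <- c(list(consensus_pwm("ACGTACGTAA", name = "planted")),
            lapply(1:4, function(i) {
              to_probabilities(rand_pwm(width = 8, name = paste0("null", i),
                                        seed = 70 + i))
            }))
  feats <- tfidf_transform(scan_pwm_counts(fx$seqs, mots))
  fold <- stratified_kfold(fx$labels, 3, seed = 2)
  fit <- train_gbdt(feats[fold != 1, ], fx$labels[fold != 1],
                    hyperparams = list(nrounds = 30, max_depth = 2), seed = 1)
  res <- perturbation_importance(fit, feats[fold == 1, ],
                                 fx$labels[fold == 1],
                                 c("planted", "null1"), n_iter = 5, seed = 3)
  expect_gte(res$f1_drop[res$feature == "planted"], 0.2)
  expect_lt(abs(res$f1_drop[res$feature == "null1"]), 0.01)
  expect_error(perturbation_importance(fit, feats, fx$labels, "ghost"),
               "unknown")
})

test_that("one-hot positional track is the channel-wise sum of squares", {
  attr_set <- structure(list(values = list(matrix(0, 5, 4)),
                             base_value = 0, seq_id = "a"),
                        class = "ltr_attr_onehot")
  tr <- positional_track_onehot(attr_set)[[1]]
  expect_equal(tr$values, rep(0, 5))
  expect_equal(tr$anchors$start, 0L)
  expect_equal(tr$anchors$end, 4L)
  # single nonzero value v at (p, c) -> track[p] = v^2
  m <- matrix(0, 6, 4)
  m[3, 2] <- -1.5
  attr_set$values <- list(m)
  expect_equal(positional_track_onehot(attr_set)[[1]]$values,
               c(0, 0, 2.25, 0, 0, 0))
  # independent summation oracle on a random tensor; squaring kills the sign
  withr::with_seed(71, {
    r <- matrix(rnorm(40), 10, 4)
    attr_set$values <- list(r)
    got <- positional_track_onehot(attr_set)[[1]]$values
    oracle <- vapply(1:10, function(p) sum(r[p, ]^2), numeric(1))
    expect_equal(got, oracle)
    attr_set$values <- list(-r)
    expect_equal(positional_track_onehot(attr_set)[[1]]$values, oracle)
  })
})

test_that("k-mer positional track averages covering tokens", {
  # uniform token attribution a -> uniform track a
  tr <- positional_track_kmer(rep(0.3, 7), k = 4)
  expect_equal(tr$values, rep(0.3, 10))
  # L = k: a single token's value everywhere
  tr2 <- positional_track_kmer(2.5, k = 6)
  expect_equal(tr2$values, rep(2.5, 6))
  # coverage-list oracle on a random case (sign preserved)
  withr::with_seed(73, {
    k <- 5
    vals <- rnorm(12)
    trk <- positional_track_kmer(vals, k = k)
    L <- 12 + k - 1
    oracle <- vapply(1:L, function(p) {
      cover <- which(seq_len(12) <= p & seq_len(12) + k - 1 >= p)
      mean(vals[cover])
    }, numeric(1))
    expect_equal(trk$values, oracle)
  })
})

test_that("k-mer importance aggregation scales the sign groups separately", {
  # single positive k-mer -> 1.0
  one <- aggregate_kmer_importance(list(c("AAAA")), list(0.4))
  expect_equal(one$scaled, 1)
  # means (2, 6) -> scaled (0, 1)
  two <- aggregate_kmer_importance(list(c("AAAA", "CCCC", "AAAA")),
                                   list(c(1, 6, 3)))
  expect_equal(two$scaled[two$kmer == "AAAA"], 0) # mean 2
  expect_equal(two$scaled[two$kmer == "CCCC"], 1) # mean 6
  # mixed signs: positive group in [0,1], negative in [-1,0], signs match
  withr::with_seed(75, {
    toks <- list(sample(c("AC", "GT", "CA", "TT"), 30, TRUE))
    vals <- list(rnorm(30))
    agg <- aggregate_kmer_importance(toks, vals)
    expect_true(all(sign(agg$scaled) == sign(agg$mean_value) |
                      agg$scaled == 0))
    if (any(agg$mean_value > 0)) expect_equal(max(agg$scaled), 1)
    if (any(agg$mean_value < 0)) expect_equal(min(agg$scaled), -1)
  })
})

test_that("the TATA heuristic finds a planted box and respects its window", {
  s <- rand_dna(1000, seed = 77)
  s <- gsub("TATA", "CGCG", s, fixed = TRUE) # clean background
  substr(s, 301, 306) <- "TATAAA"
  expect_equal(find_tata(s), 300L)
  expect_null(find_tata(strrep("C", 500)))
  # both consensus variants of TATA[AT]A are found
  s2 <- s
  substr(s2, 301, 306) <- "TATATA"
  expect_equal(find_tata(s2), 300L)
  # a box outside the search window is not reported
  s3 <- gsub("TATA", "CGCG", rand_dna(1000, seed = 78), fixed = TRUE)
  substr(s3, 51, 56) <- "TATAAA"
  expect_null(find_tata(s3))
  # anchor table: TSS defaults to TATA + 30
  anc <- find_anchors(sequence_tbl("x", s))
  expect_equal(anc$tata_pos, 300L)
  expect_equal(anc$tss_pos, 330L)
})

test_that("anchor-centered matrices window correctly and median finds spikes", {
  tr1 <- importance_track("a", c(1, 2, 3, 4, 5), list())
  cen <- center_tracks(list(tr1), anchor = "start", flank = 2)
  expect_equal(unname(cen$matrix[1, ]), c(NA, NA, 1, 2, 3))
  # median of identical tracks equals the track
  cen2 <- center_tracks(list(tr1, tr1, tr1), anchor = "start", flank = 2)
  expect_equal(cen2$profile$median, c(NA, NA, 1, 2, 3))
  # spikes exactly at the TATA anchors dominate the median profile
  withr::with_seed(79, {
    tracks <- lapply(1:9, function(i) {
      v <- abs(rnorm(200, 0, 0.05))
      a <- sample(60:140, 1)
      v[a + 1] <- 5
      importance_track(paste0("t", i), v, list(tata = a))
    })
    cen3 <- center_tracks(tracks, anchor = "tata", flank = 30)
    expect_equal(cen3$profile$offset[which.max(cen3$profile$median)], 0L)
  })
  # tracks lacking the anchor are skipped with a count; all-lacking errors
  with_tata <- importance_track("c", 1:10, list(tata = 5L))
  no_anchor <- importance_track("b", 1:10, list())
  cen4 <- center_tracks(list(with_tata, no_anchor), anchor = "tata", flank = 2)
  expect_equal(cen4$n_skipped, 1L)
  expect_equal(unname(cen4$matrix[1, ]), c(4, 5, 6, 7, 8))
  expect_error(center_tracks(list(no_anchor), anchor = "tata"), "anchor")
})

test_that("consensus assembly merges overlapping k-mers into bracket motifs", {
  expect_equal(assemble_consensus(c("TATAAA", "TATATA")), "TATA[AT]A")
  expect_equal(sort(assemble_consensus(c("AAAAAA", "CCCCCC"))),
               c("AAAAAA", "CCCCCC"))
  expect_equal(assemble_consensus(c("ACGTAC", "CGTACG"), min_overlap = 5),
               "ACGTACG")
  expect_equal(assemble_consensus(c("TATAAA", "TATATA"), iupac = TRUE),
               "TATAWA")
  expect_equal(assemble_consensus(character(0)), character(0))
  expect_error(assemble_consensus(c("AAA", "AAAA")), "equal length")
})

test_that("expected gradients are approximately additive in logit space", {
  fx <- planted_motif_fixture(n_per_class = 40, L = 120, seed = 81)
  enc <- one_hot_encode(fx$seqs, L_max = 120L)
  model <- build_cnn_lstm(n_filters = 6, filter_width = 8, pool_size = 4,
                          lstm_units = 6, task = "ltr_detection",
                          L_max = 120L, seed = 4)
  fit <- train_sequence_model(
    model,
    train = list(x = one_hot_encode(fx$seqs[1:60, ], 120L),
                 y = fx$labels[1:60]),
    validation = list(x = one_hot_encode(fx$seqs[61:80, ], 120L),
                      y = fx$labels[61:80]),
    cfg = train_config(epochs = 6, patience = 2, batch_size = 32,
                       learning_rate = 1e-2, seed = 5))
  eg <- expected_gradients(fit, enc, indices = c(1, 41), n_steps = 64)
  logits <- predict(fit, enc, type = "margin")
  for (j in 1:2) {
    i <- c(1, 41)[j]
    total <- sum(eg$values[[j]])
    gap <- logits[i] - eg$base_value[j]
    expect_lt(abs(total - gap), max(0.05 * abs(gap), 0.02))
  }
})
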