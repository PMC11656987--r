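numeric_grad <- function(f, params, eps = 1e-5) {
  out <- lapply(params, function(p) p * 0)
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      up <- params
      up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params
      dn[[nm]][i] <- dn[[nm]][i] - eps
      out[[nm]][i] <- (f(up) - f(dn)) / (2 * eps)
    }
  }
  out
}

test_that("CNN-LSTM analytic gradients match finite differences (binary task)", {
  withr::with_seed(31, {
    seqs <- rand_seq_tbl(5, L = 40, seed = 31)
    seqs$sequence[2] <- substr(seqs$sequence[2], 1, 23) # ragged lengths
    enc <- one_hot_encode(seqs, L_max = 40L)
    y <- c(1, 0, 1, 1, 0)
    w <- c(1, 1.5, 1, 0.5, 1)
    for (bidir in c(TRUE, FALSE)) {
      model <- build_cnn_lstm(n_filters = 3, filter_width = 5, pool_size = 3,
                              lstm_units = 4, task = "ltr_detection",
                              L_max = 40L, bidirectional = bidir, seed = 5)
      res <- nn_batch_grad_cpp(enc$codes, model$params, 3L, y, w, 0L, TRUE)
      f <- function(p) nn_batch_grad_cpp(enc$codes, p, 3L, y, w, 0L, FALSE)$loss
      ng <- numeric_grad(f, model$params)
      for (nm in names(model$params)) {
        denom <- pmax(abs(ng[[nm]]), 1e-4)
        expect_lt(max(abs(res$grads[[nm]] - ng[[nm]]) / denom), 1e-3)
      }
    }
  })
})

test_that("CNN-LSTM analytic gradients match finite differences (family task)", {
  withr::with_seed(33, {
    seqs <- rand_seq_tbl(4, L = 30, seed = 33)
    enc <- one_hot_encode(seqs, L_max = 30L)
    y <- c(0, 2, 1, 2)
    w <- c(1, 2, 1, 1)
    model <- build_cnn_lstm(n_filters = 2, filter_width = 4, pool_size = 2,
                            lstm_units = 3, task = "family",
                            class_names = c("a", "b", "c"), L_max = 30L,
                            seed = 7)
    res <- nn_batch_grad_cpp(enc$codes, model$params, 2L, y, w, 1L, TRUE)
    f <- function(p) nn_batch_grad_cpp(enc$codes, p, 2L, y, w, 1L, FALSE)$loss
    ng <- numeric_grad(f, model$params)
    for (nm in names(model$params)) {
      denom <- pmax(abs(ng[[nm]]), 1e-4)
      expect_lt(max(abs(res$grads[[nm]] - ng[[nm]]) / denom), 1e-3)
    }
  })
})

test_that("input gradients match finite differences and padding is inert", {
  withr::with_seed(35, {
    seqs <- rand_seq_tbl(1, L = 25, seed = 35)
    enc <- one_hot_encode(seqs, L_max = 25L)
    model <- build_cnn_lstm(n_filters = 3, filter_width = 4, pool_size = 2,
                            lstm_units = 3, task = "ltr_detection",
                            L_max = 25L, seed = 9)
    X <- one_hot_matrix(enc, 1)
    g <- nn_input_grad_cpp(X, model$params, 2L, 0L)
    eps <- 1e-5
    for (i in sample(length(X), 20)) {
      up <- X; up[i] <- up[i] + eps
      dn <- X; dn[i] <- dn[i] - eps
      fd <- (nn_input_grad_cpp(up, model$params, 2L, 0L)$logits[1, 1] -
               nn_input_grad_cpp(dn, model$params, 2L, 0L)$logits[1, 1]) /
        (2 * eps)
      expect_equal(g$dX[i], fd, tolerance = 1e-4)
    }
    # extending the padded tail never changes the output
    enc_wide <- one_hot_encode(seqs, L_max = 60L)
    l1 <- nn_logits_cpp(enc$codes, model$params, 2L)
    l2 <- nn_logits_cpp(enc_wide$codes, model$params, 2L)
    expect_equal(l1, l2, tolerance = 1e-12)
    # the all-pad input yields the bias-only response
    l0 <- nn_logits_cpp(matrix(-1L, 1, 10), model$params, 2L)
    expect_equal(l0[1, 1], model$params$b_out[1], tolerance = 1e-12)
  })
})

test_that("CNN-LSTM output shapes and parameter count are as configured", {
  model <- build_cnn_lstm(n_filters = 8, filter_width = 6, pool_size = 4,
                          lstm_units = 5, task = "family", L_max = 100L)
  # closed-form parameter count: conv (4*w*F + F), two lstm directions
  # ((F+H)*4H + 4H each), dense (2H*K + K) with K = 15 classes
  expect_equal(n_parameters(model),
               (4 * 6 * 8 + 8) + 2 * ((8 + 5) * 4 * 5 + 4 * 5) +
                 (2 * 5 * 15 + 15))
  uni <- build_cnn_lstm(n_filters = 8, filter_width = 6, pool_size = 4,
                        lstm_units = 5, task = "family", L_max = 100L,
                        bidirectional = FALSE)
  expect_equal(n_parameters(uni),
               (4 * 6 * 8 + 8) + ((8 + 5) * 4 * 5 + 4 * 5) + (5 * 15 + 15))
  seqs <- rand_seq_tbl(3, L = 50, seed = 41)
  enc <- one_hot_encode(seqs, L_max = 100L)
  logits <- nn_logits_cpp(enc$codes, model$params, 4L)
  expect_equal(dim(logits), c(3L, 15L))
  bin <- build_cnn_lstm(n_filters = 4, filter_width = 6, pool_size = 4,
                        lstm_units = 3, task = "ltr_detection", L_max = 100L)
  expect_equal(dim(nn_logits_cpp(enc$codes, bin$params, 4L)), c(3L, 1L))
})

test_that("training converges on a planted-motif task and respects patience", {
  fx <- planted_motif_fixture(n_per_class = 120, L = 150, seed = 43)
  idx <- withr::with_seed(2, sample(nrow(fx$seqs)))
  tr <- idx[1:160]
  va <- idx[161:200]
  te <- idx[201:240]
  model <- build_cnn_lstm(n_filters = 8, filter_width = 10, pool_size = 4,
                          lstm_units = 8, task = "ltr_detection", L_max = 150L,
                          seed = 3)
  fit <- train_sequence_model(
    model,
    train = list(x = one_hot_encode(fx$seqs[tr, ], 150L), y = fx$labels[tr]),
    validation = list(x = one_hot_encode(fx$seqs[va, ], 150L),
                      y = fx$labels[va]),
    cfg = train_config(epochs = 15, patience = 3, batch_size = 32,
                       learning_rate = 1e-2, seed = 4))
  expect_true(fit$fitted)
  hist <- tidy(fit)
  expect_lte(nrow(hist), 15L)
  # patience: training halts at most 3 epochs after the best epoch
  expect_lte(nrow(hist) - fit$best_epoch, 3L)
  pred <- predict(fit, one_hot_encode(fx$seqs[te, ], 150L))
  f1 <- compute_metrics(as.character(fx$labels[te]), pred,
                        averaging = "binary", positive = "TRUE")$f1
  expect_gte(f1, 0.9)
  # bit-reproducibility under the seed
  fit2 <- train_sequence_model(
    build_cnn_lstm(n_filters = 8, filter_width = 10, pool_size = 4,
                   lstm_units = 8, task = "ltr_detection", L_max = 150L,
                   seed = 3),
    train = list(x = one_hot_encode(fx$seqs[tr, ], 150L), y = fx$labels[tr]),
    validation = list(x = one_hot_encode(fx$seqs[va, ], 150L),
                      y = fx$labels[va]),
    cfg = train_config(epochs = 15, patience = 3, batch_size = 32,
                       learning_rate = 1e-2, seed = 4))
  expect_identical(fit$params, fit2$params)
})

test_that("gbdt track separates planted-motif features and is deterministic", {
  fx <- planted_motif_fixture(n_per_class = 80, L = 250, seed = 45)
  mots <- c(list(consensus_pwm("ACGTACGTAA", name = "planted")),
            lapply(1:6, function(i) {
              to_probabilities(rand_pwm(width = 8, name = paste0("noise", i),
                                        seed = 50 + i))
            }))
  counts <- scan_pwm_counts(fx$seqs, mots)
  feats <- tfidf_transform(counts)
  idx <- withr::with_seed(3, sample(nrow(feats)))
  tr <- idx[1:110]
  te <- idx[111:160]
  fit <- train_gbdt(feats[tr, ], fx$labels[tr],
                    hyperparams = list(nrounds = 50), seed = 1)
  pred <- predict(fit, feats[te, ])
  f1 <- compute_metrics(as.character(fx$labels[te]), pred,
                        averaging = "binary", positive = "TRUE")$f1
  expect_gte(f1, 0.95)
  fit2 <- train_gbdt(feats[tr, ], fx$labels[tr],
                     hyperparams = list(nrounds = 50), seed = 1)
  expect_identical(predict(fit, feats[te, ], type = "prob"),
                   predict(fit2, feats[te, ], type = "prob"))
  expect_error(train_gbdt(feats[tr, ], rep(TRUE, 110)), "single class")
  # linearly separable toy problem reaches training F1 = 1
  toy <- tibble::tibble(seq_id = sprintf("t%02d", 1:40),
                        a = c(rnorm(20, 5), rnorm(20, -5)), b = rnorm(40))
  toy_lab <- rep(c(TRUE, FALSE), each = 20)
  toy_fit <- train_gbdt(toy, toy_lab, hyperparams = list(nrounds = 20))
  expect_equal(compute_metrics(as.character(toy_lab), predict(toy_fit, toy),
                               positive = "TRUE")$f1, 1)
})

test_that("grid search scores |grid| x k configurations and picks the dominant one", {
  fx <- planted_motif_fixture(n_per_class = 50, L = 200, seed = 47)
  mots <- list(consensus_pwm("ACGTACGTAA", name = "planted"),
               to_probabilities(rand_pwm(width = 8, name = "noise", seed = 9)))
  feats <- tfidf_transform(scan_pwm_counts(fx$seqs, mots))
  grid <- list(list(nrounds = 60, max_depth = 3),
               list(nrounds = 1, max_depth = 1, eta = 0.01)) # crippled arm
  res <- grid_search_cv(feats, fx$labels, grid, k_folds = 3, seed = 1)
  expect_equal(nrow(res$results), 2L * 3L)
  expect_equal(res$best_config, 1L)
  single <- grid_search_cv(feats, fx$labels, grid[1], k_folds = 3, seed = 1)
  expect_equal(single$best_hyperparams, grid[[1]])
  expect_error(grid_search_cv(feats, fx$labels, grid, k_folds = 60), "smallest")
})

test_that("class weights follow the inverse-frequency formula", {
  expect_equal(unname(class_weights(rep(c("a", "b"), each = 10))), c(1, 1))
  w <- class_weights(c(rep("a", 90), rep("b", 10)))
  expect_equal(unname(w), c(100 / (2 * 90), 100 / (2 * 10)))
  expect_equal(unname(w["b"]), 5)
  # weighted mean of weights under label frequencies is 1
  labs <- c(rep("x", 7), rep("y", 2), rep("z", 11))
  w2 <- class_weights(labs)
  expect_equal(sum(w2[labs]) / length(labs), 1)
  expect_error(class_weights(rep("a", 5)), "2 classes")
  expect_error(class_weights(factor(c("a", "a", "b"),
                                    levels = c("a", "b", "c"))), "no observations")
})

test_that("window pooling enumerates windows with an end anchor", {
  dim_probe <- function(window, stride, L) {
    starts <- NULL
    emb <- function(s) {
      starts <<- c(starts, s)
      rep(1, 4)
    }
    res <- window_pool_embeddings(rand_dna(L, seed = L), emb, window, stride)
    list(v = res, n = length(starts))
  }
  # L = window: exactly one call
  expect_equal(dim_probe(510, 170, 510)$n, 1L)
  expect_equal(dim_probe(510, 170, 400)$n, 1L)
  # enumeration oracle: floor((L - w)/s) + 1 (+1 when the end anchor is added)
  for (L in c(1020, 1100, 850, 680)) {
    n_windows <- dim_probe(510, 170, L)$n
    base_n <- floor((L - 510) / 170) + 1
    covered <- (base_n - 1) * 170 + 510 == L
    expect_equal(n_windows, base_n + as.integer(!covered))
  }
  # constant embedder -> constant pooled vector
  expect_equal(dim_probe(510, 170, 1234)$v, rep(1, 4))
  # varying dimension violates the contract
  bad <- function(s) rep(1, sample(2:3, 1))
  expect_error(window_pool_embeddings(rand_dna(2000, seed = 1),
                                      withr::with_seed(1, bad)),
               "dimension")
})

test_that("pooled head gradients match finite differences and training separates", {
  withr::with_seed(51, {
    X <- matrix(rnorm(6 * 20), 6, 20)
    y <- c(1, 0, 1, 0, 1, 0)
    w <- rep(1, 6)
    head_m <- build_pooled_head(20, task = "ltr_detection", n_filters = 4,
                                dense_units = 5, seed = 3)
    res <- ltrlearn:::pooled_loss_grad(head_m$params, X, y, w, TRUE,
                                       head_m$config)
    f <- function(p) ltrlearn:::pooled_loss_grad(p, X, y, w, TRUE,
                                                 head_m$config)$loss
    ng <- numeric_grad(f, head_m$params)
    for (nm in names(head_m$params)) {
      denom <- pmax(abs(ng[[nm]]), 1e-4)
      expect_lt(max(abs(res$grads[[nm]] - ng[[nm]]) / denom), 1e-3)
    }
  })

  # embeddings whose k-mer content differs by class are separable
  fx <- planted_motif_fixture(n_per_class = 100, L = 400, motif = "ACGTACGTAA",
                              n_plant = 8, seed = 53)
  emb <- kmer_hash_embedder(dim = 128, k = 6)
  E <- pooled_embedding_matrix(fx$seqs, emb)
  idx <- withr::with_seed(5, sample(nrow(E)))
  tr <- idx[1:120]
  va <- idx[121:160]
  te <- idx[161:200]
  head_m <- build_pooled_head(128, task = "ltr_detection", seed = 1)
  fit <- train_sequence_model(head_m,
                              train = list(x = E[tr, ], y = fx$labels[tr]),
                              validation = list(x = E[va, ], y = fx$labels[va]),
                              cfg = train_config(epochs = 30, patience = 8,
                                                 batch_size = 32,
                                                 learning_rate = 3e-2,
                                                 seed = 2))
  pred <- predict(fit, E[te, ])
  f1 <- compute_metrics(as.character(fx$labels[te]), pred,
                        averaging = "binary", positive = "TRUE")$f1
  expect_gte(f1, 0.9)
  # deterministic under seed
  fit2 <- train_sequence_model(build_pooled_head(128, task = "ltr_detection",
                                                 seed = 1),
                               train = list(x = E[tr, ], y = fx$labels[tr]),
                               validation = list(x = E[va, ], y = fx$labels[va]),
                               cfg = train_config(epochs = 30, patience = 8,
                                                  batch_size = 32,
                                                  learning_rate = 3e-2,
                                                  seed = 2))
  expect_identical(fit$params, fit2$params)
})

test_that("held-out F1 is non-decreasing in planted signal strength", {
  sweep_f1 <- function(seed) {
    sweep_sets <- difficulty_sweep(
      synthetic_spec(n_positive = 240, n_negative = 240,
                     length_range = c(200L, 500L),
                     neg_proportions = c(random = 0.5, markov = 0.5),
                     seed = seed),
      signal_strengths = c(0, 0.5, 1))
    vapply(sweep_sets, function(ds) {
      seqs <- dplyr::bind_rows(ds$positives, ds$negatives[names(ds$positives)])
      labels <- seqs$is_ltr
      feats <- tfidf_transform(scan_pwm_counts(seqs, ds$motifs,
                                               rel_threshold = 0.8))
      fold <- stratified_kfold(labels, 3, seed = 7)
      fit <- train_gbdt(feats[fold != 1, ], labels[fold != 1],
                        hyperparams = list(nrounds = 150, max_depth = 3),
                        seed = 1)
      compute_metrics(as.character(labels[fold == 1]),
                      predict(fit, feats[fold == 1, ]),
                      averaging = "binary", positive = "TRUE")$f1
    }, numeric(1))
  }
  f1s <- rowMeans(vapply(c(11, 12, 13), sweep_f1, numeric(3)))
  expect_true(all(diff(f1s) >= -1e-9))
  expect_gt(f1s[3], f1s[1])
  expect_gte(f1s[3], 0.9)
})
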