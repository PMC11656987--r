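test_that("filter normalization matches element-wise evaluation of the formula", {
  withr::with_seed(7, {
    S <- matrix(rnorm(32), 8, 4)
    res <- normalize_filter(S, lambda = 3)
    oracle <- exp(3 * S / max(S))
    expect_lt(max(abs(res$normalized - oracle)), 1e-12)
    # the global maximum maps to e^lambda before per-column normalization
    expect_equal(max(res$normalized), exp(3))
    # PWM columns sum to 1 and preserve each column's argmax
    expect_equal(unname(colSums(res$pwm$matrix)), rep(1, 8))
    for (j in 1:8) {
      expect_equal(unname(which.max(res$pwm$matrix[, j])), which.max(S[j, ]))
    }
  })
  # constant filter -> uniform PWM
  resc <- normalize_filter(matrix(1, 5, 4))
  expect_equal(unname(resc$pwm$matrix), matrix(0.25, 4, 5))
  # all-non-positive filter is shifted, not rejected
  resn <- normalize_filter(matrix(-abs(rnorm(20)), 5, 4))
  expect_true(all(is.finite(resn$normalized)))
})

test_that("normalization is order-preserving within each position", {
  withr::with_seed(9, {
    S <- matrix(rnorm(48), 12, 4)
    res <- normalize_filter(S, lambda = 3)
    for (j in 1:12) {
      expect_equal(order(res$normalized[j, ]), order(S[j, ]))
    }
  })
})

test_that("motif matching scores identity and reverse complement at 1", {
  q <- to_probabilities(rand_pwm(width = 8, name = "q", seed = 3))
  t_rc <- ltrlearn:::reverse_complement_pwm(q)
  t_other <- to_probabilities(rand_pwm(width = 8, name = "other", seed = 12))
  hits <- match_motifs(list(q), list(q, t_rc, t_other), min_overlap = 5)
  self <- hits[hits$target == "q", ]
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_equal(self$offset, 0L)
  expect_equal(self$orientation, "+")
  rc <- hits[hits$target == "q_rc", ]
  expect_equal(rc$score, 1, tolerance = 1e-12)
  expect_equal(rc$orientation, "-")
  # uniform query: degenerate columns score 0
  uni <- pwm_motif("uni", matrix(0.25, 4, 8), "probabilities")
  h2 <- match_motifs(list(uni), list(t_other), min_overlap = 5)
  expect_equal(h2$score, 0)
})

test_that("edge tetramer tally matches brute-force substring extraction", {
  seqs <- sequence_tbl("one", "TGTTAAACCGGGAACA")
  tal <- edge_tetramers(seqs)
  expect_equal(tal$t5, "TGTT")
  expect_equal(tal$t3, "AACA")
  expect_equal(tal$count, 1L)

  big <- rand_seq_tbl(1000, L = 30, seed = 13)
  tal2 <- edge_tetramers(big)
  expect_equal(sum(tal2$count), 1000L)
  oracle <- table(paste(substr(big$sequence, 1, 4),
                        substr(big$sequence, 27, 30)))
  got <- setNames(tal2$count, paste(tal2$t5, tal2$t3))
  expect_equal(sort(got), sort(unname(oracle)), ignore_attr = TRUE)
  for (nm in names(oracle)) expect_equal(unname(got[nm]), unname(oracle[nm]))

  # short sequences are skipped with a count
  mix <- sequence_tbl(c("long", "short"), c("TGTTCCCCAACA", "ACGTAACA"))
  mix$sequence[2] <- "ACGTAAC" # length 7 < 8
  tal3 <- edge_tetramers(mix)
  expect_equal(attr(tal3, "n_skipped"), 1L)
})

test_that("complementarity counts reverse-complement matches position-wise", {
  expect_equal(complementarity("TGTT", "AACA"), 4L)
  expect_equal(complementarity("TGTA", "AACA"), 3L)
  expect_equal(complementarity("AAAA", "AAAA"), 0L)
  expect_equal(complementarity("TGAT", "ATCA"), 4L)
  expect_error(complementarity("TGNN", "AACA"), "ACGT")
})

test_that("canonical assignment reproduces the documented shift rules", {
  a <- assign_canonical("GTTA", "AACA")
  expect_equal(c(a$canonical_t5, a$canonical_t3), c("TGTT", "AACA"))
  expect_true(a$shifted)
  b <- assign_canonical("TGTT", "AACA")
  expect_false(b$shifted)
  expect_equal(c(b$canonical_t5, b$canonical_t3), c("TGTT", "AACA"))
  d <- assign_canonical("GATA", "ATCA")
  expect_equal(c(d$canonical_t5, d$canonical_t3), c("TGAT", "ATCA"))
  expect_true(d$shifted)
  # a shift never decreases complementarity relative to identity
  withr::with_seed(17, {
    for (i in 1:200) {
      t5 <- rand_dna(4)
      t3 <- rand_dna(4)
      asg <- assign_canonical(t5, t3)
      expect_gte(asg$complementarity, complementarity(t5, t3))
    }
  })
})

test_that("edge summaries conserve counts and percentages sum to ~100", {
  single <- tibble::tibble(t5 = "TGTT", t3 = "AACA", count = 10L)
  s1 <- summarize_edges(single)
  expect_equal(s1$percent, 100L)
  withr::with_seed(19, {
    for (i in 1:20) {
      tal <- tibble::tibble(t5 = vapply(1:8, function(j) rand_dna(4), ""),
                            t3 = vapply(1:8, function(j) rand_dna(4), ""),
                            count = sample(1:500, 8))
      top_n <- sample(3:8, 1)
      sm <- summarize_edges(tal, top_n = top_n)
      top <- utils::head(dplyr::arrange(tal, dplyr::desc(count)), top_n)
      expect_equal(sum(sm$total), sum(top$count)) # conservation
      expect_lte(abs(sum(sm$percent) - 100L), nrow(sm) - 1L)
    }
  })
})

test_that("trained CNN filters recover a planted motif PWM (3-seed majority)", {
  # class-1 sequences all carry the consensus; a filter should align to it
  consensus <- "TGACGTCATTGG"
  fx <- planted_motif_fixture(n_per_class = 150, L = 200, motif = consensus,
                              n_plant = 3, seed = 23)
  idx_tr <- withr::with_seed(1, sample(nrow(fx$seqs), 240))
  idx_va <- setdiff(seq_len(nrow(fx$seqs)), idx_tr)
  target <- consensus_pwm(consensus, strength = 0.97)
  best_score <- function(seed) {
    # forward-only recurrence: with a single direction each planted motif
    # concentrates in one first-layer filter instead of being shared
    model <- build_cnn_lstm(n_filters = 12, filter_width = 12, pool_size = 4,
                            lstm_units = 12, task = "ltr_detection",
                            L_max = 200L, bidirectional = FALSE,
                            forget_bias = 1, seed = seed)
    fit <- train_sequence_model(
      model,
      train = list(x = one_hot_encode(fx$seqs[idx_tr, ], 200L),
                   y = fx$labels[idx_tr]),
      validation = list(x = one_hot_encode(fx$seqs[idx_va, ], 200L),
                        y = fx$labels[idx_va]),
      cfg = train_config(epochs = 12, patience = 4, batch_size = 32,
                         learning_rate = 1e-2, seed = seed + 1))
    filt <- extract_filters(fit)
    expect_length(filt, 12L)
    # filter f, position j, channel b maps to conv_W row (j-1)*4 + b
    expect_equal(filt[[3]][2, 4], fit$params$conv_W[(2 - 1) * 4 + 4, 3],
                 ignore_attr = TRUE)
    hits <- match_motifs(filters_to_motifs(fit), list(target), min_overlap = 6)
    max(hits$score) # best-offset per-column correlation
  }
  scores <- vapply(c(2, 5, 8), best_score, numeric(1))
  expect_gte(sum(scores >= 0.7), 2L) # majority of seeds recover the motif
})
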