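# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (brute force / enumeration) and never share
# code with the implementation paths they check.

rand_dna <- function(L, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

rand_seq_tbl <- function(n, L = 100L, seed = 1L, prefix = "s") {
  withr::with_seed(seed, {
    sequence_tbl(sprintf("%s%03d", prefix, seq_len(n)),
                 vapply(rep(L, n), function(l) {
                   paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                         collapse = "")
                 }, character(1)))
  })
}

rand_pwm <- function(width = 6L, name = "m", seed = 1L, kind = "counts") {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(4 * width, 5) + 1, 4, width)
    if (kind == "counts") return(pwm_motif(name, m, "counts"))
    pwm_motif(name, sweep(m, 2, colSums(m), "/"), "probabilities")
  })
}

# Brute-force PWM occurrence counter re-deriving the threshold semantics
# from scratch in plain R.
oracle_scan_count <- function(sequence, motif, rel_threshold = 0.8,
                              background = rep(0.25, 4), pseudocount = 0.8) {
  if (motif$kind == "counts") {
    m <- motif$matrix + pseudocount
    q <- sweep(m, 2, colSums(m), "/")
  } else {
    eps <- pseudocount / 100
    q <- sweep(motif$matrix + eps * background, 2, 1 + eps, "/")
  }
  sc <- log2(q / background)
  w <- ncol(sc)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L < w) return(0L)
  lo <- sum(apply(sc, 2, min))
  hi <- sum(apply(sc, 2, max))
  thr <- lo + rel_threshold * (hi - lo)
  count <- 0L
  for (p in 1:(L - w + 1)) {
    win <- chars[p:(p + w - 1)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    s <- sum(vapply(seq_len(w), function(j) {
      sc[match(win[j], c("A", "C", "G", "T")), j]
    }, numeric(1)))
    if (s >= thr - 1e-12) count <- count + 1L
  }
  count
}

# Exact global-alignment identity oracle (Needleman-Wunsch, matches /
# alignment length), independent of the Biostrings path.
oracle_global_identity <- function(a, b, match = 1, mismatch = -1,
                                   gap_open = 5, gap_ext = 2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = gap_open, gapExtension = gap_ext)
  list(identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln))
}

# Mutate a sequence to approximately the requested identity.
mutate_seq <- function(s, rate, seed = 1L) {
  withr::with_seed(seed, {
    chars <- strsplit(s, "")[[1]]
    flip <- runif(length(chars)) < rate
    chars[flip] <- vapply(which(flip), function(i) {
      sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }, character(1))
    paste(chars, collapse = "")
  })
}

# 3-mer frequency vector of a string.
kmer_freqs <- function(s, k = 3L) {
  km <- substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  tab <- table(factor(km, levels = do.call(paste0, rev(expand.grid(
    rep(list(c("A", "C", "G", "T")), k), stringsAsFactors = FALSE)))))
  as.numeric(tab) / sum(tab)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Small planted-motif classification fixture: positives carry `n_plant`
# instances of the motif consensus, negatives are plain random sequences.
planted_motif_fixture <- function(n_per_class = 60L, L = 300L,
                                  motif = "ACGTACGTAA", n_plant = 2L,
                                  seed = 7L) {
  withr::with_seed(seed, {
    w <- nchar(motif)
    mk_pos <- function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      for (p in sample(seq(10, L - w - 10), n_plant)) {
        substr(s, p, p + w - 1) <- motif
      }
      s
    }
    pos <- vapply(seq_len(n_per_class), mk_pos, character(1))
    neg <- vapply(seq_len(n_per_class), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    list(seqs = sequence_tbl(sprintf("p%03d", seq_len(2 * n_per_class)),
                             c(pos, neg),
                             is_ltr = rep(c(TRUE, FALSE), each = n_per_class)),
         labels = rep(c(TRUE, FALSE), each = n_per_class),
         motif_name = "planted")
  })
}

consensus_pwm <- function(consensus, name = "planted", strength = 0.9) {
  w <- nchar(consensus)
  cons <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - strength) / 3, 4, w)
  m[cbind(cons, seq_len(w))] <- strength
  pwm_motif(name, m, "probabilities")
}

# Brute-force Shapley oracle for tree ensembles: coalition enumeration with
# cover-weighted conditional expectations, reconstructed from the dumped tree
# structures (independent of the predcontrib path).
oracle_tree_shap <- function(model, x) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$booster))
  feats <- model$feature_names
  expvalue <- function(tree_df, node_id, S) {
    row <- tree_df[tree_df$ID == node_id, ]
    if (row$Feature == "Leaf") return(row$Gain)
    if (row$Feature %in% S) {
      nxt <- if (x[[row$Feature]] < row$Split) row$Yes else row$No
      return(expvalue(tree_df, nxt, S))
    }
    cl <- tree_df$Cover[tree_df$ID == row$Yes]
    cr <- tree_df$Cover[tree_df$ID == row$No]
    (cl * expvalue(tree_df, row$Yes, S) +
        cr * expvalue(tree_df, row$No, S)) / (cl + cr)
  }
  v <- function(S) {
    sum(vapply(unique(dt$Tree), function(tr) {
      tree_df <- dt[dt$Tree == tr, ]
      expvalue(tree_df, tree_df$ID[tree_df$Node == 0], S)
    }, numeric(1)))
  }
  M <- length(feats)
  phi <- setNames(numeric(M), feats)
  subsets <- unlist(lapply(0:M, function(k) {
    utils::combn(feats, k, simplify = FALSE)
  }), recursive = FALSE)
  for (f in feats) {
    for (S in subsets) {
      if (f %in% S) next
      wgt <- factorial(length(S)) * factorial(M - length(S) - 1) / factorial(M)
      phi[f] <- phi[f] + wgt * (v(c(S, f)) - v(S))
    }
  }
  phi
}


# Exact two-sided Wilcoxon signed-rank p by enumerating all sign vectors.
oracle_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_lo <- mean(v_all <= v_obs + 1e-12)
  p_hi <- mean(v_all >= v_obs - 1e-12)
  min(1, 2 * min(p_lo, p_hi))
}
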