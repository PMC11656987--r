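# Explainability layer: Shapley-value attributions (exact TreeSHAP for the
# tree ensemble, permutation-sampling estimates for arbitrary predictors,
# integrated/expected gradients for the network), their positional
# aggregations, perturbation importance, promoter anchor prediction,
# anchor-centered track matrices, and consensus assembly of important k-mers.

#' Exact Shapley attributions for the tree-ensemble model
#'
#' Polynomial-time TreeSHAP on the fitted gradient-boosted ensemble, in
#' margin (log-odds) space. Additivity is exact: the base value plus the
#' per-feature attributions reproduce each margin prediction.
#'
#' @param model A fitted `ltr_gbdt`.
#' @param features Feature tibble.
#' @return An object of class `ltr_attr_features`: `values` (n x p matrix;
#'   for the family task a list of such matrices, one per class),
#'   `base_value`, `feature_names`, `seq_id`.
#' @export
tree_shap <- function(model, features) {
  if (!inherits(model, "ltr_gbdt")) {
    abort("tree_shap needs a fitted tree-ensemble (`ltr_gbdt`) model")
  }
  x <- feature_matrix_values(features)[, model$feature_names, drop = FALSE]
  dm <- xgboost::xgb.DMatrix(x, nthread = 1)
  contrib <- predict(model$booster, dm, predcontrib = TRUE)
  p <- length(model$feature_names)
  if (length(dim(contrib)) == 3L) {
    vals <- lapply(seq_len(dim(contrib)[2]), function(k) {
      m <- contrib[, k, seq_len(p), drop = TRUE]
      m <- matrix(m, nrow = nrow(x))
      colnames(m) <- model$feature_names
      m
    })
    names(vals) <- model$class_names
    base <- contrib[1, , p + 1]
  } else {
    vals <- contrib[, seq_len(p), drop = FALSE]
    colnames(vals) <- model$feature_names
    base <- contrib[1, p + 1]
  }
  structure(list(values = vals, base_value = base,
                 feature_names = model$feature_names,
                 seq_id = features$seq_id),
            class = "ltr_attr_features")
}

#' Model-agnostic Shapley attribution by permutation sampling
#'
#' Monte-Carlo Shapley estimate: features are revealed in random order on
#' top of a background sample, and each feature is credited with the change
#' in model output when it is revealed. Deterministic under `seed`;
#' additivity holds up to Monte-Carlo error.
#'
#' @param predict_fn Function `matrix -> numeric` (one output per row).
#' @param instances Numeric matrix (or feature tibble) of instances to
#'   explain.
#' @param background Numeric matrix of background rows (the "feature absent"
#'   reference distribution).
#' @param n_samples Number of sampled permutations per instance.
#' @param bg_per_perm Background rows averaged over per permutation.
#' @param seed Integer seed.
#' @return An `ltr_attr_features` with `values` (n x p) and `base_value`
#'   (mean model output on the background).
#' @export
model_agnostic_shap <- function(predict_fn, instances, background,
                                n_samples = 50L, bg_per_perm = 10L,
                                seed = 1L) {
  seq_id <- NULL
  if (is.data.frame(instances)) {
    seq_id <- instances[["seq_id"]]
    instances <- feature_matrix_values(instances)
  }
  if (is.data.frame(background)) background <- feature_matrix_values(background)
  background <- as.matrix(background)
  if (nrow(background) == 0L) abort("`background` must be non-empty")
  instances <- as.matrix(instances)
  p <- ncol(instances)
  phi <- matrix(0, nrow(instances), p, dimnames = list(NULL, colnames(instances)))
  with_seed(seed, {
    for (i in seq_len(nrow(instances))) {
      x <- instances[i, ]
      acc <- numeric(p)
      for (s in seq_len(n_samples)) {
        perm <- sample.int(p)
        nb <- min(bg_per_perm, nrow(background))
        bgi <- background[sample.int(nrow(background), nb), , drop = FALSE]
        # per background row: rows 1..p+1 reveal the permuted features on top
        # of that row; all grids are stacked into one predict call
        grids <- lapply(seq_len(nb), function(b) {
          grid <- matrix(bgi[b, ], p + 1L, p, byrow = TRUE)
          for (j in seq_len(p)) {
            grid[(j + 1L):(p + 1L), perm[j]] <- x[perm[j]]
          }
          grid
        })
        f <- predict_fn(do.call(rbind, grids))
        fm <- matrix(f, nrow = p + 1L)
        acc[perm] <- acc[perm] + rowMeans(matrix(apply(fm, 2, diff), nrow = p))
      }
      phi[i, ] <- acc / n_samples
    }
  })
  base <- mean(predict_fn(background))
  structure(list(values = phi, base_value = base,
                 feature_names = colnames(instances), seq_id = seq_id),
            class = "ltr_attr_features")
}

#' Perturbation importance of named features
#'
#' Each listed feature column is replaced by i.i.d. uniform draws on
#' `[0, max(F_i)]`; the model is re-scored and the mean F1 drop over
#' `n_iter` random iterations reported. A feature the model ignores drops
#' (close to) nothing; an all-zero column is reported as a 0 drop.
#'
#' @param model A fitted classifier with a [predict()] method returning
#'   class labels.
#' @param features Feature tibble of the evaluation set.
#' @param labels True labels for the evaluation set.
#' @param feature_names Features to perturb (e.g. the top-k by mean |SHAP|).
#' @param n_iter Random iterations per feature (default 5).
#' @param seed Integer seed.
#' @param averaging F1 averaging.
#' @return A tibble `feature`, `baseline_f1`, `perturbed_f1`, `f1_drop`.
#' @export
perturbation_importance <- function(model, features, labels, feature_names,
                                    n_iter = 5L, seed = 1L,
                                    averaging = "binary") {
  stopifnot(n_iter >= 1)
  missing_f <- setdiff(feature_names, names(features))
  if (length(missing_f) > 0L) {
    abort(sprintf("unknown features: %s", paste(missing_f, collapse = ", ")))
  }
  labels_chr <- as.character(labels)
  baseline <- compute_metrics(labels_chr, predict(model, features),
                              averaging = averaging)$f1
  n <- nrow(features)
  rows <- lapply(seq_along(feature_names), function(k) {
    fn <- feature_names[[k]]
    mx <- max(features[[fn]])
    scores <- with_seed(derive_seed(seed, k), {
      vapply(seq_len(n_iter), function(it) {
        pert <- features
        pert[[fn]] <- runif(n, 0, mx)
        compute_metrics(labels_chr, predict(model, pert),
                        averaging = averaging)$f1
      }, numeric(1))
    })
    tibble(feature = fn, baseline_f1 = baseline,
           perturbed_f1 = mean(scores), f1_drop = baseline - mean(scores))
  })
  dplyr::bind_rows(rows)
}

# ---------------------------------------------------------------------------
# Network attributions

#' Expected-gradients attribution for the CNN-LSTM
#'
#' Integrated gradients from the all-zero (absent/padding) baseline in logit
#' space: per position and channel, the input value times the average input
#' gradient along the straight path from baseline to input. Satisfies
#' additivity (completeness) up to quadrature error in `n_steps`.
#'
#' @param model A fitted `ltr_cnn_lstm`.
#' @param batch An `ltr_onehot` batch.
#' @param indices Which sequences of the batch to attribute (default all).
#' @param n_steps Path quadrature steps.
#' @param class_idx Output class index for the family task (1-based;
#'   binary tasks use the single logit).
#' @return An object of class `ltr_attr_onehot`: `values` (list of L x 4
#'   matrices over the unpadded positions), `base_value` (logit of the empty
#'   input), `seq_id`.
#' @export
expected_gradients <- function(model, batch, indices = NULL, n_steps = 16L,
                               class_idx = 1L) {
  stopifnot(inherits(model, "ltr_cnn_lstm"), inherits(batch, "ltr_onehot"))
  if (is.null(indices)) indices <- seq_along(batch$seq_id)
  pool <- model$config$pool_size
  vals <- vector("list", length(indices))
  base <- numeric(length(indices))
  for (ii in seq_along(indices)) {
    i <- indices[[ii]]
    X <- one_hot_matrix(batch, i)
    if (nrow(X) == 0L) {
      vals[[ii]] <- matrix(0, 0, 4)
      base[ii] <- nn_logits_cpp(matrix(-1L, 1, 1), model$params,
                                pool)[1, class_idx]
      next
    }
    avg_grad <- matrix(0, nrow(X), 4)
    for (s in seq_len(n_steps)) {
      a <- (s - 0.5) / n_steps
      g <- nn_input_grad_cpp(a * X, model$params, pool, class_idx - 1L)
      avg_grad <- avg_grad + g$dX
    }
    vals[[ii]] <- X * (avg_grad / n_steps)
    # completeness is relative to the all-zero input of the same length
    base[ii] <- nn_input_grad_cpp(0 * X, model$params, pool,
                                  class_idx - 1L)$logits[1, class_idx]
  }
  structure(list(values = vals, base_value = base,
                 seq_id = batch$seq_id[indices]),
            class = "ltr_attr_onehot")
}

# ---------------------------------------------------------------------------
# Importance tracks

#' Construct a per-position importance track
#'
#' @param seq_id Sequence identifier.
#' @param values Numeric vector, one value per (unpadded) position.
#' @param anchors Named list of 0-based anchor positions among `start`,
#'   `tata`, `tss`, `end` (`NULL` entries allowed).
#' @return An object of class `ltr_track`.
#' @export
importance_track <- function(seq_id, values, anchors = list()) {
  L <- length(values)
  anchors <- utils::modifyList(list(start = 0L, tata = NULL, tss = NULL,
                                    end = L - 1L), anchors)
  structure(list(seq_id = seq_id, values = values, anchors = anchors),
            class = "ltr_track")
}

#' Positional importance from one-hot attributions
#'
#' The per-position track is the sum of squared attribution values over the
#' four channels (padded positions are excluded by construction).
#'
#' @param attribs An `ltr_attr_onehot`.
#' @param anchors Optional anchor tibble (`seq_id`, `tata_pos`, `tss_pos`).
#' @return A list of `ltr_track` objects.
#' @export
positional_track_onehot <- function(attribs, anchors = NULL) {
  stopifnot(inherits(attribs, "ltr_attr_onehot"))
  purrr::map2(attribs$values, attribs$seq_id, function(m, id) {
    v <- rowSums(m^2)
    importance_track(id, v, anchor_list_for(id, anchors))
  })
}

#' Positional importance from k-mer token attributions
#'
#' Each position's value is the mean attribution of every token whose k-mer
#' span covers it (1 to k tokens near the sequence edges).
#'
#' @param token_values Numeric vector of per-token attributions
#'   (length `L - k + 1`).
#' @param k Token k-mer size.
#' @param seq_id Sequence identifier.
#' @param anchors Optional anchor tibble.
#' @return An `ltr_track` of length `L`.
#' @export
positional_track_kmer <- function(token_values, k, seq_id = "seq",
                                  anchors = NULL) {
  n_tok <- length(token_values)
  L <- n_tok + k - 1L
  cs <- c(0, cumsum(token_values))
  pos <- seq_len(L)
  lo <- pmax(1L, pos - k + 1L)
  hi <- pmin(pos, n_tok)
  vals <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  importance_track(seq_id, vals, anchor_list_for(seq_id, anchors))
}

anchor_list_for <- function(id, anchors) {
  if (is.null(anchors)) return(list())
  row <- anchors[anchors$seq_id == id, , drop = FALSE]
  if (nrow(row) == 0L) return(list())
  out <- list()
  if (!is.null(row$tata_pos) && !is.na(row$tata_pos[1])) out$tata <- row$tata_pos[1]
  if (!is.null(row$tss_pos) && !is.na(row$tss_pos[1])) out$tss <- row$tss_pos[1]
  out
}

#' Aggregate token attributions into scaled k-mer importance
#'
#' Per distinct k-mer, the mean attribution over all occurrences across the
#' instances; the positive-mean group is min-max scaled to [0, 1] and the
#' negative-mean group to [-1, 0] (a single-member group maps to the extreme
#' value of its sign).
#'
#' @param tokens List over instances of character token vectors.
#' @param values List over instances of numeric attribution vectors aligned
#'   with `tokens`.
#' @return A tibble `kmer`, `mean_value`, `n`, `scaled`.
#' @export
aggregate_kmer_importance <- function(tokens, values) {
  stopifnot(length(tokens) == length(values), length(tokens) >= 1L)
  df <- tibble(kmer = unlist(tokens), value = unlist(values))
  agg <- df |>
    dplyr::group_by(.data$kmer) |>
    dplyr::summarise(mean_value = mean(.data$value), n = dplyr::n(),
                     .groups = "drop")
  scale_group <- function(x, sign) {
    if (length(x) == 0L) return(numeric(0))
    rng <- range(x)
    if (diff(rng) == 0) return(rep(sign, length(x)))
    if (sign > 0) (x - rng[1]) / diff(rng) else (x - rng[2]) / diff(rng)
  }
  pos <- agg$mean_value > 0
  neg <- agg$mean_value < 0
  agg$scaled <- 0
  agg$scaled[pos] <- scale_group(agg$mean_value[pos], 1)
  agg$scaled[neg] <- scale_group(agg$mean_value[neg], -1)
  dplyr::arrange(agg, dplyr::desc(abs(.data$scaled)))
}

# ---------------------------------------------------------------------------
# Anchors

# TATAWA probability matrix used by the internal TATA-box heuristic.
tata_pwm <- function() {
  strong <- function(b) {
    v <- rep(0.03, 4)
    v[match(b, DNA_BASES)] <- 0.91
    v
  }
  w_col <- c(0.455, 0.045, 0.045, 0.455)
  m <- cbind(strong("T"), strong("A"), strong("T"), strong("A"), w_col,
             strong("A"))
  pwm_motif("TATAWA", m, "probabilities")
}

#' Locate a TATA box inside a sequence window
#'
#' Offline stand-in for an external promoter predictor: the degenerate
#' pattern TATAWA (W = A/T) is scored PWM-style inside the configured
#' central window; the best-scoring position is returned, or `NULL` when no
#' position reaches `rel_threshold` of the score range.
#'
#' @param sequence A DNA string.
#' @param window Fraction range of the sequence searched (default the
#'   central 20–80%).
#' @param rel_threshold Score-range fraction a hit must reach.
#' @return 0-based position of the best hit, or `NULL`.
#' @export
find_tata <- function(sequence, window = c(0.2, 0.8), rel_threshold = 0.85) {
  s <- normalize_sequence(sequence)
  L <- nchar(s)
  lo <- max(0L, floor(window[1] * L))
  hi <- min(L, ceiling(window[2] * L))
  if (hi - lo < 6L) return(NULL)
  sub <- substr(s, lo + 1L, hi)
  hits <- scan_pwm_positions(sub, tata_pwm(), rel_threshold = rel_threshold)
  if (length(hits) == 0L) return(NULL)
  cd <- seq_to_codes(sub)
  cd[is.na(cd)] <- -1L
  sc <- pwm_log_odds(tata_pwm())
  scores <- vapply(hits, function(p) {
    sum(sc[cbind(cd[(p + 1):(p + 6)] + 1L, 1:6)])
  }, numeric(1))
  lo + hits[which.max(scores)]
}

#' Predict TATA/TSS anchors for a sequence table
#'
#' TATA positions come from [find_tata()]; the TSS defaults to the TATA
#' position + `tss_offset` (canonical TATA-to-TSS spacing) when not supplied
#' by an anchor file.
#'
#' @param seqs A sequence tibble.
#' @param anchor_file Optional TSV (`seq_id`, `tata_pos`, `tss_pos`, 0-based)
#'   overriding the heuristic.
#' @param tss_offset Default TATA-to-TSS spacing in bases.
#' @param ... Passed to [find_tata()].
#' @return A tibble `seq_id`, `tata_pos`, `tss_pos` (NA when not found).
#' @export
find_anchors <- function(seqs, anchor_file = NULL, tss_offset = 30L, ...) {
  assert_sequence_tbl(seqs)
  out <- tibble(
    seq_id = seqs$id,
    tata_pos = vapply(seqs$sequence, function(s) {
      p <- find_tata(s, ...)
      if (is.null(p)) NA_integer_ else as.integer(p)
    }, integer(1), USE.NAMES = FALSE)
  )
  out$tss_pos <- out$tata_pos + tss_offset
  if (!is.null(anchor_file)) {
    ext <- utils::read.delim(anchor_file, header = TRUE,
                             stringsAsFactors = FALSE)
    m <- match(out$seq_id, ext$seq_id)
    take <- !is.na(m)
    if (!is.null(ext$tata_pos)) out$tata_pos[take] <- ext$tata_pos[m[take]]
    if (!is.null(ext$tss_pos)) out$tss_pos[take] <- ext$tss_pos[m[take]]
  }
  out
}

#' Center importance tracks on an anchor
#'
#' Rows are tracks windowed to `anchor +/- flank` (cells outside the
#' sequence are `NA`); the median profile is taken per column over non-`NA`
#' cells. Tracks lacking the anchor are skipped and counted.
#'
#' @param tracks List of `ltr_track` objects.
#' @param anchor One of `"start"`, `"tata"`, `"tss"`, `"end"`.
#' @param flank Flank size in bases.
#' @return A list: `matrix` (tracks x offsets, dimnames give offsets),
#'   `profile` (tibble `offset`, `median`), `n_skipped`.
#' @export
center_tracks <- function(tracks, anchor = c("start", "tata", "tss", "end"),
                          flank = 50L) {
  anchor <- match.arg(anchor)
  has <- vapply(tracks, function(tr) !is.null(tr$anchors[[anchor]]), logical(1))
  if (!any(has)) abort(sprintf("no track has the '%s' anchor", anchor))
  used <- tracks[has]
  offs <- (-flank):flank
  m <- matrix(NA_real_, length(used), length(offs),
              dimnames = list(vapply(used, function(tr) tr$seq_id, character(1)),
                              offs))
  for (i in seq_along(used)) {
    tr <- used[[i]]
    a <- tr$anchors[[anchor]]
    pos <- a + offs # 0-based positions
    ok <- pos >= 0 & pos < length(tr$values)
    m[i, ok] <- tr$values[pos[ok] + 1L]
  }
  profile <- tibble(offset = offs,
                    median = unname(apply(m, 2, median, na.rm = TRUE)))
  list(matrix = m, profile = profile, n_skipped = sum(!has))
}

# ---------------------------------------------------------------------------
# Consensus assembly

#' Assemble consensus motifs from overlapping k-mers
#'
#' Greedy chaining in the given order (use decreasing |score|): a k-mer is
#' merged into an existing stack when some relative offset aligns it to a
#' stack member with at least `min_overlap` matching positions (the best
#' offset by matches, then by smallest shift, wins). Stacked variants at the
#' same column become character classes: `[XY]` bracket notation, or IUPAC
#' codes with `iupac = TRUE`.
#'
#' @param kmers Character vector of equal-length k-mers, ordered by
#'   decreasing importance.
#' @param min_overlap Minimum matching positions to merge (default k - 2).
#' @param iupac Emit IUPAC degeneracy codes instead of brackets.
#' @return Character vector of consensus motifs, one per connected
#'   component, in input order of their seeds.
#' @export
assemble_consensus <- function(kmers, min_overlap = NULL, iupac = FALSE) {
  if (length(kmers) == 0L) return(character(0))
  k <- unique(nchar(kmers))
  if (length(k) != 1L) abort("all k-mers must have equal length")
  if (is.null(min_overlap)) min_overlap <- k - 2L
  if (min_overlap >= k) abort("`min_overlap` must be smaller than k")
  # components: list of tibble(kmer, offset)
  comps <- list()
  n_match_at <- function(a, b, shift) {
    # b placed `shift` columns right of a
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    if (shift >= 0) {
      ov <- k - shift
      if (ov <= 0) return(0L)
      sum(ca[(shift + 1):k] == cb[1:ov])
    } else {
      n_match_at(b, a, -shift)
    }
  }
  for (km in kmers) {
    placed <- FALSE
    for (ci in seq_along(comps)) {
      best <- NULL
      for (j in seq_len(nrow(comps[[ci]]))) {
        other <- comps[[ci]]$kmer[j]
        base_off <- comps[[ci]]$offset[j]
        for (shift in (-(k - min_overlap)):(k - min_overlap)) {
          mm <- n_match_at(other, km, shift)
          if (mm >= min_overlap) {
            cand <- list(matches = mm, shift = abs(shift),
                         offset = base_off + shift)
            if (is.null(best) || cand$matches > best$matches ||
                (cand$matches == best$matches && cand$shift < best$shift)) {
              best <- cand
            }
          }
        }
      }
      if (!is.null(best)) {
        comps[[ci]] <- dplyr::bind_rows(comps[[ci]],
                                        tibble(kmer = km, offset = best$offset))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      comps[[length(comps) + 1L]] <- tibble(kmer = km, offset = 0L)
    }
  }
  vapply(comps, consensus_string, character(1), k = k, iupac = iupac)
}

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                 ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

consensus_string <- function(comp, k, iupac) {
  lo <- min(comp$offset)
  hi <- max(comp$offset) + k - 1L
  cols <- lapply(lo:hi, function(col) {
    lets <- character(0)
    for (j in seq_len(nrow(comp))) {
      rel <- col - comp$offset[j]
      if (rel >= 0 && rel < k) {
        lets <- c(lets, substr(comp$kmer[j], rel + 1L, rel + 1L))
      }
    }
    sort(unique(lets))
  })
  paste(vapply(cols, function(lets) {
    if (length(lets) == 1L) return(lets)
    if (iupac) return(unname(IUPAC_CODES[paste(lets, collapse = "")]))
    paste0("[", paste(lets, collapse = ""), "]")
  }, character(1)), collapse = "")
}
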