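# CNN first-layer filter -> motif pipeline, and the LTR 5'/3' edge tetramer
# analysis (canonical TG..CA pair assignment with 1-bp shift correction).

#' Extract first-layer convolution filters from a trained CNN-LSTM
#'
#' @param model A fitted `ltr_cnn_lstm`.
#' @return A list of raw filter matrices (width x 4, columns A, C, G, T).
#' @export
extract_filters <- function(model) {
  stopifnot(inherits(model, "ltr_cnn_lstm"))
  if (!model$fitted) abort("model is not fitted; train it before extracting filters")
  W <- model$params$conv_W # (4*wf) x F, rows j*4 + base
  wf <- model$config$filter_width
  lapply(seq_len(ncol(W)), function(f) {
    m <- matrix(W[, f], nrow = 4)
    out <- t(m) # width x 4
    colnames(out) <- DNA_BASES
    out
  })
}

#' Normalize a convolution filter into a PWM
#'
#' The filter is normalized as `exp(lambda * S / max(S))` with the global
#' matrix maximum and scaling factor `lambda` (default 3), then each column
#' is normalized to probabilities for PWM export. A filter with
#' `max(S) <= 0` is first shifted by its maximum so the normalization is
#' defined.
#'
#' @param S Raw filter matrix (width x 4).
#' @param lambda Positive scaling factor.
#' @param per_column Use per-column maxima instead of the global maximum.
#' @param name Motif name for the exported PWM.
#' @return A list: `normalized` (width x 4, entries in (0, e^lambda]) and
#'   `pwm` (an `ltr_pwm` probability motif).
#' @export
normalize_filter <- function(S, lambda = 3, per_column = FALSE,
                             name = "filter") {
  S <- as.matrix(S)
  stopifnot(ncol(S) == 4L, lambda > 0)
  if (max(S) <= 0) S <- S - max(S) + 1 # shift so the normalization is defined
  denom <- if (per_column) {
    matrix(apply(S, 1, max), nrow(S), 4)
  } else {
    max(S)
  }
  S_hat <- exp(lambda * S / denom)
  prob <- S_hat / rowSums(S_hat)
  list(normalized = S_hat,
       pwm = pwm_motif(name, t(prob), "probabilities"))
}

#' Export normalized CNN filters as motifs
#'
#' @param model A fitted `ltr_cnn_lstm`.
#' @param lambda Scaling factor for [normalize_filter()].
#' @return A list of `ltr_pwm` probability motifs (one per filter), ready
#'   for [write_meme()] or [match_motifs()].
#' @export
filters_to_motifs <- function(model, lambda = 3) {
  filt <- extract_filters(model)
  lapply(seq_along(filt), function(i) {
    normalize_filter(filt[[i]], lambda = lambda,
                     name = sprintf("filter_%03d", i))$pwm
  })
}

reverse_complement_pwm <- function(motif) {
  m <- motif$matrix[4:1, rev(seq_len(motif$width)), drop = FALSE]
  rownames(m) <- DNA_BASES
  pwm_motif(paste0(motif$name, "_rc"), m, motif$kind)
}

#' Match query motifs against a target motif database
#'
#' Internal motif comparison (an offline stand-in for suite tools like
#' Tomtom): the score of a query/target pair is the maximum over offsets and
#' both orientations of the mean per-column Pearson correlation on the
#' overlapping columns (overlap >= `min_overlap`). Degenerate
#' (zero-variance) columns contribute correlation 0.
#'
#' @param queries,targets Lists of `ltr_pwm` probability motifs.
#' @param min_overlap Minimum overlapping columns.
#' @param top_n Matches retained per query.
#' @return A tibble `query`, `target`, `offset`, `orientation`, `score`,
#'   ranked per query.
#' @export
match_motifs <- function(queries, targets, min_overlap = 5L, top_n = 5L) {
  pair_score <- function(q, t) {
    best <- list(score = -Inf, offset = NA_integer_, orientation = "+")
    for (orient in c("+", "-")) {
      tm <- if (orient == "+") t else reverse_complement_pwm(t)
      wq <- q$width
      wt <- tm$width
      for (off in (-(wt - min_overlap)):(wq - min_overlap)) {
        qcols <- max(1, off + 1):min(wq, off + wt)
        if (length(qcols) < min_overlap) next
        tcols <- qcols - off
        cors <- vapply(seq_along(qcols), function(j) {
          a <- q$matrix[, qcols[j]]
          b <- tm$matrix[, tcols[j]]
          if (sd(a) == 0 || sd(b) == 0) return(0)
          cor(a, b)
        }, numeric(1))
        sc <- mean(cors)
        if (sc > best$score) {
          best <- list(score = sc, offset = off, orientation = orient)
        }
      }
    }
    best
  }
  rows <- list()
  for (q in queries) {
    if (q$width < min_overlap) {
      warn(sprintf("query %s narrower than min_overlap; skipped", q$name))
      next
    }
    hits <- lapply(targets, function(t) {
      b <- pair_score(q, t)
      tibble(query = q$name, target = t$name, offset = b$offset,
             orientation = b$orientation, score = b$score)
    })
    hits <- dplyr::bind_rows(hits) |>
      dplyr::arrange(dplyr::desc(.data$score)) |>
      utils::head(top_n)
    rows[[length(rows) + 1L]] <- hits
  }
  dplyr::bind_rows(rows)
}

# ---------------------------------------------------------------------------
# Edge tetramer analysis

#' Tally 5'/3' terminal tetramer pairs
#'
#' Counts the exact (first 4 bases, last 4 bases) pair of every sequence of
#' length >= 8; shorter sequences are skipped and counted.
#'
#' @param seqs A sequence tibble.
#' @return A tibble `t5`, `t3`, `count` in descending count order; skipped
#'   sequences in attribute `n_skipped`.
#' @export
edge_tetramers <- function(seqs) {
  assert_sequence_tbl(seqs)
  L <- nchar(seqs$sequence)
  ok <- L >= 8L
  t5 <- substr(seqs$sequence[ok], 1L, 4L)
  t3 <- substring(seqs$sequence[ok], L[ok] - 3L)
  out <- tibble(t5 = t5, t3 = t3) |>
    dplyr::count(.data$t5, .data$t3, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$t5, .data$t3)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Base complementarity of a terminal tetramer pair
#'
#' The number of positions at which the 3' tetramer equals the reverse
#' complement of the 5' tetramer (4 for a perfect LTR edge pair such as
#' TGTT..AACA).
#'
#' @param t5,t3 Length-4 strings over A/C/G/T.
#' @return Integer in 0..4.
#' @export
complementarity <- function(t5, t3) {
  if (nchar(t5) != 4L || nchar(t3) != 4L ||
      grepl("[^ACGT]", t5) || grepl("[^ACGT]", t3)) {
    abort("tetramers must be length-4 strings over ACGT")
  }
  rc <- revcomp(t5)
  sum(strsplit(rc, "")[[1]] == strsplit(t3, "")[[1]])
}

#' Assign a tetramer pair to its canonical form
#'
#' Corrects 1-base annotation shifts: the candidate set is the identity, the
#' 5'-shifted pair (`T` prepended, last base dropped), the 3'-shifted pair
#' (first base dropped, `A` appended) and both. The winner maximises
#' (presence of the canonical TG prefix and CA suffix, then edge
#' complementarity); the identity wins ties, and `shifted` records whether a
#' shift was applied.
#'
#' @param t5,t3 Length-4 tetramers over ACGT.
#' @return A one-row tibble `t5`, `t3`, `canonical_t5`, `canonical_t3`,
#'   `shifted`, `complementarity`.
#' @export
assign_canonical <- function(t5, t3) {
  cand5 <- c(t5, paste0("T", substr(t5, 1, 3)))
  cand3 <- c(t3, paste0(substr(t3, 2, 4), "A"))
  cands <- expand.grid(i5 = 1:2, i3 = 1:2)
  best <- NULL
  for (r in seq_len(nrow(cands))) {
    c5 <- cand5[cands$i5[r]]
    c3 <- cand3[cands$i3[r]]
    canon <- startsWith(c5, "TG") && endsWith(c3, "CA")
    comp <- complementarity(c5, c3)
    is_id <- cands$i5[r] == 1L && cands$i3[r] == 1L
    key <- c(as.numeric(canon), comp, as.numeric(is_id))
    if (is.null(best) ||
        key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2]) ||
        (key[1] == best$key[1] && key[2] == best$key[2] && key[3] > best$key[3])) {
      best <- list(c5 = c5, c3 = c3, key = key, is_id = is_id, comp = comp)
    }
  }
  tibble(t5 = t5, t3 = t3, canonical_t5 = best$c5, canonical_t3 = best$c3,
         shifted = !best$is_id, complementarity = best$comp)
}

#' Summarize an edge tetramer tally by canonical pair
#'
#' Takes the `top_n` most frequent pairs, assigns each to its canonical pair
#' via [assign_canonical()], sums counts per canonical pair, and reports
#' integer-rounded percentages of the summarized counts.
#'
#' @param tally Tibble from [edge_tetramers()] (`t5`, `t3`, `count`), or any
#'   tibble of that shape (e.g. published counts).
#' @param top_n Number of most frequent pairs summarized (default 5).
#' @return An object of class `ltr_edge_summary`: tibble `canonical_t5`,
#'   `canonical_t3`, `total`, `percent`, `complementarity`; the per-pair
#'   assignment in attribute `assignment`.
#' @export
summarize_edges <- function(tally, top_n = 5L) {
  if (nrow(tally) == 0L) abort("empty tally")
  top <- utils::head(dplyr::arrange(tally, dplyr::desc(.data$count)), top_n)
  asg <- dplyr::bind_rows(purrr::map2(top$t5, top$t3, assign_canonical))
  asg$count <- top$count
  out <- asg |>
    dplyr::group_by(.data$canonical_t5, .data$canonical_t3) |>
    dplyr::summarise(total = sum(.data$count),
                     complementarity = .data$complementarity[1],
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total))
  out$percent <- as.integer(round(100 * out$total / sum(out$total)))
  out <- out[, c("canonical_t5", "canonical_t3", "total", "percent",
                 "complementarity")]
  attr(out, "assignment") <- asg
  class(out) <- c("ltr_edge_summary", class(out))
  out
}

#' @method tidy ltr_edge_summary
#' @export
tidy.ltr_edge_summary <- function(x, ...) attr(x, "assignment")
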