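# Featurization tracks: PWM (TFBS) occurrence counts with TF-IDF weighting,
# one-hot encoding for the CNN-LSTM, k-mer tokenization, and the classical
# k-mer Jaccard comparison.

# Per-base log-odds score matrix for one motif. Counts get the pseudocount
# added before normalisation; probability motifs are smoothed toward the
# background by pseudocount/width weight so log() never sees a zero.
pwm_log_odds <- function(motif, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(inherits(motif, "ltr_pwm"))
  if (motif$kind == "counts") {
    m <- motif$matrix + pseudocount
    q <- sweep(m, 2, colSums(m), "/")
  } else {
    eps <- pseudocount / 100
    q <- sweep(motif$matrix + eps * background, 2, 1 + eps, "/")
  }
  log2(q / background)
}

#' Scan sequences for PWM motif occurrences
#'
#' Slides each motif's log-odds window along the forward strand of each
#' sequence and counts positions whose score reaches
#' `min + rel_threshold * (max - min)` of the motif's attainable score range.
#' Windows containing unknown bases (N) never match. With
#' `both_strands = TRUE` the reverse complement is scanned too (off by
#' default: LTRs are orientation-defined).
#'
#' @param seqs A sequence tibble.
#' @param motifs List of `ltr_pwm` objects.
#' @param rel_threshold Fraction of the score range in (0, 1].
#' @param background Background base probabilities (A, C, G, T).
#' @param pseudocount Added to counts before log-odds conversion.
#' @param both_strands Also scan the reverse complement.
#' @return A feature tibble: `seq_id` plus one count column per motif, with
#'   attribute `kind = "counts"`.
#' @export
scan_pwm_counts <- function(seqs, motifs, rel_threshold = 0.8,
                            background = rep(0.25, 4), pseudocount = 0.8,
                            both_strands = FALSE) {
  assert_sequence_tbl(seqs)
  if (!is_scalar_fraction(rel_threshold) || rel_threshold <= 0) {
    abort("`rel_threshold` must be in (0, 1]")
  }
  codes <- lapply(seqs$sequence, function(s) {
    cd <- seq_to_codes(s)
    cd[is.na(cd)] <- -1L
    cd
  })
  scores <- lapply(motifs, pwm_log_odds, background = background,
                   pseudocount = pseudocount)
  counts <- if (length(motifs) == 0L) {
    matrix(0L, nrow(seqs), 0L)
  } else {
    scan_pwm_counts_cpp(codes, scores, rel_threshold)
  }
  if (both_strands && length(motifs) > 0L) {
    rc_codes <- lapply(seqs$sequence, function(s) {
      cd <- seq_to_codes(revcomp(s))
      cd[is.na(cd)] <- -1L
      cd
    })
    counts <- counts + scan_pwm_counts_cpp(rc_codes, scores, rel_threshold)
  }
  nm <- vapply(motifs, function(m) m$name, character(1))
  colnames(counts) <- nm
  out <- dplyr::bind_cols(tibble(seq_id = seqs$id), as_tibble(counts))
  attr(out, "kind") <- "counts"
  out
}

#' Positions of PWM occurrences in one sequence
#'
#' Companion to [scan_pwm_counts()] returning 0-based match offsets for one
#' motif in one sequence (same threshold semantics).
#'
#' @inheritParams scan_pwm_counts
#' @param sequence A single DNA string.
#' @param motif One `ltr_pwm`.
#' @return Integer vector of 0-based start offsets.
#' @export
scan_pwm_positions <- function(sequence, motif, rel_threshold = 0.8,
                               background = rep(0.25, 4), pseudocount = 0.8) {
  cd <- seq_to_codes(normalize_sequence(sequence))
  cd[is.na(cd)] <- -1L
  scan_pwm_positions_cpp(cd, pwm_log_odds(motif, background, pseudocount),
                         rel_threshold)
}

feature_matrix_values <- function(features) {
  as.matrix(features[, setdiff(names(features), "seq_id"), drop = FALSE])
}

#' TF-IDF transform a count feature table
#'
#' Smoothed inverse document frequency `idf(t) = ln((1+N)/(1+df(t))) + 1`
#' with `df` the number of sequences in which the motif occurs at least once,
#' followed by L2 normalisation of each row. Downweights ubiquitous,
#' unspecific binding sites. All-zero rows stay zero.
#'
#' @param features A count feature tibble from [scan_pwm_counts()].
#' @param idf Optional precomputed idf vector (use the training idf when
#'   transforming held-out data).
#' @return A feature tibble with attribute `kind = "tfidf"` and the idf used
#'   stored in attribute `idf`.
#' @export
tfidf_transform <- function(features, idf = NULL) {
  if (!identical(attr(features, "kind"), "counts")) {
    abort("`features` must be a counts feature table")
  }
  m <- feature_matrix_values(features)
  if (is.null(idf)) {
    n <- nrow(m)
    df <- colSums(m > 0)
    idf <- log((1 + n) / (1 + df)) + 1
  }
  v <- sweep(m, 2, idf, "*")
  norms <- sqrt(rowSums(v^2))
  norms[norms == 0] <- 1
  v <- v / norms
  out <- dplyr::bind_cols(tibble(seq_id = features$seq_id), as_tibble(v))
  attr(out, "kind") <- "tfidf"
  attr(out, "idf") <- idf
  out
}

#' One-hot encode sequences for the CNN-LSTM
#'
#' Unknown bases (N) are removed before encoding; sequences longer than
#' `L_max` keep their 5'-most `L_max` bases, shorter ones are padded at the
#' 3' end with all-zero rows. The padded positions are masked out of every
#' downstream model pass.
#'
#' @param seqs A sequence tibble.
#' @param L_max Maximum encoded length (default 4000).
#' @return An object of class `ltr_onehot`: integer code matrix (`codes`,
#'   n x L_max with -1 for padding), logical `mask`, `lengths`, and `seq_id`.
#' @export
one_hot_encode <- function(seqs, L_max = 4000L) {
  assert_sequence_tbl(seqs)
  stopifnot(L_max > 0)
  n <- nrow(seqs)
  codes <- matrix(-1L, n, L_max)
  lens <- integer(n)
  for (i in seq_len(n)) {
    cd <- seq_to_codes(seqs$sequence[[i]])
    cd <- cd[!is.na(cd)] # drop N
    if (length(cd) == 0L) {
      warn(sprintf("sequence %s contains only unknown bases; encoded as all-pad",
                   seqs$id[[i]]))
    }
    if (length(cd) > L_max) cd <- cd[seq_len(L_max)]
    lens[i] <- length(cd)
    if (length(cd) > 0L) codes[i, seq_along(cd)] <- cd
  }
  structure(list(codes = codes, mask = sweep(col(codes), 1, lens, "<="),
                 lengths = lens, seq_id = seqs$id, L_max = as.integer(L_max)),
            class = "ltr_onehot")
}

#' Materialise the dense one-hot matrix of one encoded sequence
#'
#' @param batch An `ltr_onehot` batch.
#' @param i Row index.
#' @param pad Include the padded all-zero rows up to `L_max`.
#' @return A numeric matrix (length x 4), rows summing to 1 on real positions.
#' @export
one_hot_matrix <- function(batch, i, pad = FALSE) {
  stopifnot(inherits(batch, "ltr_onehot"))
  L <- if (pad) batch$L_max else batch$lengths[i]
  m <- matrix(0, L, 4, dimnames = list(NULL, DNA_BASES))
  len <- batch$lengths[i]
  if (len > 0L) {
    cd <- batch$codes[i, seq_len(len)]
    m[cbind(seq_len(len), cd + 1L)] <- 1
  }
  m
}

#' Tokenize a sequence into overlapping k-mers
#'
#' Stride-1 overlapping k-mers in 5' to 3' order; an empty token vector when
#' the sequence is shorter than `k`.
#'
#' @param sequence A DNA string.
#' @param k k-mer size (the embedding track uses 4, 5 or 6).
#' @return Character vector of `max(L - k + 1, 0)` tokens.
#' @export
kmer_tokenize <- function(sequence, k = 6L) {
  stopifnot(k >= 1)
  s <- normalize_sequence(sequence)
  L <- nchar(s)
  if (L < k) return(character(0))
  substring(s, 1:(L - k + 1L), k:L)
}

#' Jaccard similarity of pooled k-mer sets
#'
#' Distinct k-mers are pooled across the sequences on each side;
#' the index is `|A intersect B| / |A union B|` (0 when both sides are
#' empty).
#'
#' @param seqs_a,seqs_b Sequence tibbles (or character vectors of sequences).
#' @param k k-mer size (default 6).
#' @return A single fraction in [0, 1].
#' @export
jaccard_kmer <- function(seqs_a, seqs_b, k = 6L) {
  stopifnot(k >= 1)
  get_seqs <- function(x) {
    if (is.data.frame(x)) x$sequence else as.character(x)
  }
  pool <- function(x) {
    unique(unlist(lapply(get_seqs(x), function(s) {
      distinct_kmers(normalize_sequence(s), k)
    })))
  }
  a <- pool(seqs_a)
  b <- pool(seqs_b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}
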