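# Dataset curation: CD-HIT-style greedy redundancy clustering, solo-LTR
# screening of the negative set, and stratified train/validation/test splits.

# Global alignment identity: matches / alignment length (gaps included).
pair_identity_global <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# Cheap shared-k-mer containment used to skip hopeless alignments.
kmer_containment <- function(kmers_a, kmers_b) {
  if (length(kmers_a) == 0L || length(kmers_b) == 0L) return(0)
  length(intersect(kmers_a, kmers_b)) / min(length(kmers_a), length(kmers_b))
}

#' Greedy identity clustering of sequences
#'
#' CD-HIT-style greedy incremental clustering: sequences are sorted by length
#' (descending, ties by id); each sequence joins the first existing cluster
#' whose representative it matches at `identity >= threshold`, otherwise it
#' founds a new cluster. Identity is matches / alignment length of a global
#' alignment, with a shared-k-mer screen (word size `word_size`) before each
#' alignment. The representative is the longest member (ties by id).
#'
#' @param seqs A sequence tibble.
#' @param threshold Identity threshold in [0.5, 1].
#' @param word_size k-mer size of the pre-alignment screen.
#' @return A tibble with columns `id`, `cluster`, `representative`,
#'   `is_representative`; attribute `threshold`.
#' @export
greedy_identity_cluster <- function(seqs, threshold, word_size = 8L) {
  assert_sequence_tbl(seqs)
  if (!is_scalar_fraction(threshold, 0.5, 1.0)) {
    abort("`threshold` must lie in [0.5, 1.0]")
  }
  if (nrow(seqs) == 0L) abort("`seqs` must be non-empty")
  ord <- order(-nchar(seqs$sequence), seqs$id)
  ids <- seqs$id[ord]
  sq <- seqs$sequence[ord]
  kmers <- lapply(sq, distinct_kmers, k = word_size)
  # identity t keeps roughly t^word_size of the k-mers intact; half that is a
  # conservative screen that never rejects a qualifying pair in practice
  screen_cut <- 0.5 * threshold^word_size
  rep_idx <- integer(0)
  cluster_of <- integer(length(ids))
  for (i in seq_along(ids)) {
    assigned <- 0L
    for (ci in seq_along(rep_idx)) {
      r <- rep_idx[ci]
      if (kmer_containment(kmers[[i]], kmers[[r]]) < screen_cut) next
      if (pair_identity_global(sq[i], sq[r]) >= threshold) {
        assigned <- ci
        break
      }
    }
    if (assigned == 0L) {
      rep_idx <- c(rep_idx, i)
      assigned <- length(rep_idx)
    }
    cluster_of[i] <- assigned
  }
  out <- tibble(
    id = ids,
    cluster = cluster_of,
    representative = ids[rep_idx[cluster_of]],
    is_representative = ids == ids[rep_idx[cluster_of]]
  )
  out <- out[match(seqs$id, out$id), ]
  attr(out, "threshold") <- threshold
  out
}

#' Select one representative sequence per cluster
#'
#' Deterministic: the longest member of each cluster, ties broken by
#' lexicographic id (which is how the greedy clustering chose its founders).
#'
#' @param seqs The sequence tibble that was clustered.
#' @param assignment Output of [greedy_identity_cluster()].
#' @return A sequence tibble with one row per cluster.
#' @export
select_representatives <- function(seqs, assignment) {
  assert_sequence_tbl(seqs)
  reps <- assignment$representative[!duplicated(assignment$cluster)]
  out <- seqs[match(sort(unique(reps)), seqs$id), ]
  out[order(match(out$id, reps)), ]
}

#' Screen negatives for solo-LTR contamination
#'
#' A negative sequence is removed when a local alignment to any sequence of
#' the LTR database reaches `identity >= min_identity` over at least
#' `min_coverage` of that LTR's length. A shared-11-mer prefilter skips
#' alignments that cannot qualify. The 80/80 defaults echo the conventional
#' family-definition thresholds.
#'
#' @param negatives,ltr_db Sequence tibbles.
#' @param min_identity,min_coverage Fractions in (0, 1].
#' @return A list with sequence tibbles `kept` and `removed`
#'   (`kept` + `removed` = `negatives`).
#' @export
solo_ltr_screen <- function(negatives, ltr_db, min_identity = 0.8,
                            min_coverage = 0.8) {
  assert_sequence_tbl(negatives, "negatives")
  assert_sequence_tbl(ltr_db, "ltr_db")
  if (nrow(ltr_db) == 0L) {
    return(list(kept = negatives, removed = negatives[0, ]))
  }
  ltr_kmers <- lapply(ltr_db$sequence, distinct_kmers, k = 11L)
  hit <- vapply(seq_len(nrow(negatives)), function(i) {
    neg <- negatives$sequence[[i]]
    nk <- distinct_kmers(neg, 11L)
    for (j in seq_len(nrow(ltr_db))) {
      if (length(intersect(nk, ltr_kmers[[j]])) == 0L) next
      ltr <- ltr_db$sequence[[j]]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(neg), Biostrings::DNAString(ltr),
        type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = FALSE),
        gapOpening = 5, gapExtension = 2)
      ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
      cover <- Biostrings::width(Biostrings::subject(aln)) / nchar(ltr)
      if (ident >= min_identity && cover >= min_coverage) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(kept = negatives[!hit, ], removed = negatives[hit, ])
}

# Largest-remainder allocation of n items to fractions (deviation < 1 item).
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Proportions are preserved within one sequence per stratum (largest-
#' remainder allocation); the assignment is reproducible under `seed`.
#' Strata smaller than 3 go wholly to the training set with a warning.
#'
#' @param seqs A sequence tibble.
#' @param fractions Named numeric `(train, validation, test)` summing to 1.
#' @param stratify_by Label column used for stratification.
#' @param seed Integer seed.
#' @return A list of sequence tibbles `train`, `validation`, `test`.
#' @export
split_dataset <- function(seqs, fractions = c(train = 0.7, validation = 0.1,
                                              test = 0.2),
                          stratify_by = "is_ltr", seed = 1L) {
  assert_sequence_tbl(seqs)
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0)) {
    abort("`fractions` must be positive and sum to 1")
  }
  lab <- seqs[[stratify_by]]
  if (any(is.na(lab))) abort(sprintf("missing `%s` labels", stratify_by))
  assign3 <- rep(NA_integer_, nrow(seqs))
  with_seed(seed, {
    for (lv in unique(lab)) {
      idx <- which(lab == lv)
      if (length(idx) < 3L) {
        warn(sprintf("stratum '%s' has fewer than 3 sequences; assigned to train", lv))
        assign3[idx] <- 1L
        next
      }
      idx <- sample(idx)
      cnt <- allocate_counts(length(idx), fractions)
      assign3[idx] <- rep(1:3, times = cnt)
    }
  })
  list(train = seqs[assign3 == 1L, ],
       validation = seqs[assign3 == 2L, ],
       test = seqs[assign3 == 3L, ])
}
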