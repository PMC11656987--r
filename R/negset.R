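# LTR-negative training-set construction: uniform-random sequences,
# genomic-like windows, and cluster-wise order-2 Markov resamples of the
# positive set (composition preserved, spatial organisation destroyed).

all_contexts <- function(order) {
  if (order == 0L) return("")
  do.call(paste0, rev(expand.grid(rep(list(DNA_BASES), order),
                                  stringsAsFactors = FALSE)))
}

#' Train a Markov chain model on DNA sequences
#'
#' Transition probabilities are pseudocount-smoothed empirical frequencies:
#' `P(b | c) = (count(cb) + pseudocount) / (count(c.) + 4 * pseudocount)`.
#' The initial distribution is the empirical distribution of each sequence's
#' first `order` bases.
#'
#' @param seqs A sequence tibble (or character vector of sequences).
#' @param order Chain order (default 2, matching the negative-set recipe).
#' @param pseudocount Smoothing mass for unseen contexts.
#' @return An object of class `ltr_markov` with `transition`
#'   (4^order x 4 matrix, rows named by context), `initial`, `order`,
#'   `pseudocount`, and the empirical `lengths` of the training sequences.
#' @export
train_markov <- function(seqs, order = 2L, pseudocount = 0.5) {
  sq <- if (is.data.frame(seqs)) seqs$sequence else as.character(seqs)
  stopifnot(order >= 1)
  sq <- vapply(sq, normalize_sequence, character(1), USE.NAMES = FALSE)
  usable <- nchar(sq) > order
  if (!any(usable)) abort("all sequences are shorter than order + 1")
  contexts <- all_contexts(order)
  counts <- matrix(0, length(contexts), 4,
                   dimnames = list(contexts, DNA_BASES))
  init <- setNames(numeric(length(contexts)), contexts)
  n_ctx <- length(contexts)
  for (s in sq[usable]) {
    cd <- seq_to_codes(s)
    ok <- !is.na(cd)
    L <- length(cd)
    # context index (1-based) at positions order+1 .. L
    pow <- 4^((order - 1):0)
    idx_ok <- rep(TRUE, L - order)
    ctx_idx <- rep(1L, L - order)
    for (j in seq_len(order)) {
      cj <- cd[j:(L - order + j - 1L)]
      idx_ok <- idx_ok & !is.na(cj)
      cj[is.na(cj)] <- 0L
      ctx_idx <- ctx_idx + cj * pow[j]
    }
    nxt <- cd[(order + 1L):L]
    keep <- idx_ok & !is.na(nxt)
    if (any(keep)) {
      tab <- table(factor(ctx_idx[keep], levels = seq_len(n_ctx)),
                   factor(nxt[keep] + 1L, levels = 1:4))
      counts <- counts + as.matrix(tab)
    }
    if (all(ok[seq_len(order)])) {
      first_idx <- 1L + sum(cd[seq_len(order)] * pow)
      init[first_idx] <- init[first_idx] + 1
    }
  }
  trans <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  if (pseudocount == 0) trans[rowSums(counts) == 0, ] <- 0.25
  if (sum(init) == 0) init[] <- 1 / n_ctx else init <- init / sum(init)
  structure(list(transition = trans, initial = init, order = as.integer(order),
                 pseudocount = pseudocount,
                 lengths = nchar(sq[usable])),
            class = "ltr_markov")
}

#' Generate a sequence from a Markov model
#'
#' The first `order` bases are drawn from the initial distribution, each
#' following base from the context's transition row. Deterministic under
#' `seed`.
#'
#' @param model An `ltr_markov` model.
#' @param length Target sequence length (> order).
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @return A single DNA string.
#' @export
generate_markov <- function(model, length, seed = NULL) {
  stopifnot(inherits(model, "ltr_markov"), length > model$order)
  order <- model$order
  cum_trans <- t(apply(model$transition, 1, cumsum))
  cum_init <- cumsum(model$initial)
  with_seed(seed, {
    first <- findInterval(runif(1), cum_init) + 1L
    ctx_codes <- seq_to_codes(rownames(model$transition)[first])
    out <- integer(length)
    out[seq_len(order)] <- ctx_codes
    state <- first
    mod_base <- 4^(order - 1L)
    u <- runif(length - order)
    for (t in (order + 1L):length) {
      b <- findInterval(u[t - order], cum_trans[state, ]) + 1L
      b <- min(b, 4L)
      out[t] <- b - 1L
      state <- ((state - 1L) %% mod_base) * 4L + b
    }
    codes_to_seq(out)
  })
}

# Uniform-random sequence of given length.
random_dna <- function(length) {
  codes_to_seq(sample.int(4L, length, replace = TRUE) - 1L)
}

#' Sample genomic windows avoiding excluded intervals
#'
#' Draws `n` windows by rejection sampling from the supplied contigs, never
#' overlapping an excluded interval (0-based, half-open coordinates).
#'
#' @param genome_seqs Sequence tibble of contigs.
#' @param exclude Data frame with columns `seq_id`, `start`, `end`
#'   (0-based half-open), or `NULL`.
#' @param n Number of windows.
#' @param length_sampler Function `n -> integer lengths`, or a numeric vector
#'   to sample lengths from.
#' @param seed Integer seed.
#' @param max_tries Rejection budget per requested window.
#' @return A sequence tibble of windows with ids `<seq_id>:<start>-<end>`.
#' @export
sample_genomic_windows <- function(genome_seqs, exclude = NULL, n,
                                   length_sampler, seed = NULL,
                                   max_tries = 1000L) {
  assert_sequence_tbl(genome_seqs, "genome_seqs")
  draw_len <- if (is.function(length_sampler)) {
    length_sampler
  } else {
    function(m) sample(as.integer(length_sampler), m, replace = TRUE)
  }
  contig_len <- nchar(genome_seqs$sequence)
  with_seed(seed, {
    out_id <- character(n)
    out_seq <- character(n)
    got <- 0L
    tries <- 0L
    budget <- max_tries * max(n, 1L)
    while (got < n) {
      if (tries >= budget) {
        abort("could not place the requested windows outside the excluded regions")
      }
      tries <- tries + 1L
      ci <- sample.int(nrow(genome_seqs), 1L)
      L <- draw_len(1L)
      if (L > contig_len[ci]) next
      start <- sample.int(contig_len[ci] - L + 1L, 1L) - 1L # 0-based
      end <- start + L
      if (!is.null(exclude)) {
        ex <- exclude[exclude$seq_id == genome_seqs$id[ci], , drop = FALSE]
        if (nrow(ex) > 0 && any(start < ex$end & ex$start < end)) next
      }
      got <- got + 1L
      out_id[got] <- sprintf("%s:%d-%d", genome_seqs$id[ci], start, end)
      out_seq[got] <- substr(genome_seqs$sequence[ci], start + 1L, end)
    }
    sequence_tbl(out_id, out_seq, is_ltr = FALSE)
  })
}

#' Compose an LTR-negative training set
#'
#' Builds the three negative classes: `markov` (order-2 Markov resamples of
#' clusters of the positive set — LTR-like 3-mer composition without the
#' spatial organisation), `random` (uniform base composition) and `genomic`
#' (windows of supplied genome contigs). Markov models are trained per
#' cluster of the positives (greedy identity clustering at
#' `cluster_threshold`, default 0.70); generated lengths follow each source
#' cluster's empirical length distribution.
#'
#' @param ltrs Positive (LTR) sequence tibble.
#' @param genome_seqs Contig tibble, required when the genomic share is
#'   positive.
#' @param proportions Named fractions for `genomic`, `random`, `markov`
#'   summing to 1.
#' @param cluster_threshold Identity threshold for clustering the positives.
#' @param n_total Total number of negatives.
#' @param seed Integer seed.
#' @param clusters Optional precomputed grouping of `ltrs` (vector, one label
#'   per row) that bypasses alignment clustering, e.g. known family labels.
#' @param order,pseudocount Markov model settings.
#' @param exclude Excluded intervals forwarded to
#'   [sample_genomic_windows()].
#' @return A sequence tibble with an extra `neg_class` column; per-class
#'   counts in attribute `class_counts`.
#' @export
compose_negative_set <- function(ltrs, genome_seqs = NULL,
                                 proportions = c(genomic = 1/3, random = 1/3,
                                                 markov = 1/3),
                                 cluster_threshold = 0.70, n_total, seed = 1L,
                                 clusters = NULL, order = 2L,
                                 pseudocount = 0.5, exclude = NULL) {
  assert_sequence_tbl(ltrs, "ltrs")
  proportions <- proportions[c("genomic", "random", "markov")]
  proportions[is.na(proportions)] <- 0
  names(proportions) <- c("genomic", "random", "markov")
  if (abs(sum(proportions) - 1) > 1e-9) abort("`proportions` must sum to 1")
  counts <- allocate_counts(n_total, proportions)
  names(counts) <- names(proportions)
  if (counts[["genomic"]] > 0 && is.null(genome_seqs)) {
    abort("a positive genomic share needs `genome_seqs`")
  }
  lens <- nchar(ltrs$sequence)
  pieces <- list()

  if (counts[["genomic"]] > 0) {
    g <- sample_genomic_windows(genome_seqs, exclude = exclude,
                                n = counts[["genomic"]],
                                length_sampler = lens,
                                seed = derive_seed(seed, 1L))
    g$id <- sprintf("neg_genomic_%04d", seq_len(nrow(g)))
    g$neg_class <- "genomic"
    pieces$genomic <- g
  }
  if (counts[["random"]] > 0) {
    r <- with_seed(derive_seed(seed, 2L), {
      rl <- sample(lens, counts[["random"]], replace = TRUE)
      sequence_tbl(sprintf("neg_random_%04d", seq_len(counts[["random"]])),
                   vapply(rl, random_dna, character(1)), is_ltr = FALSE)
    })
    r$neg_class <- "random"
    pieces$random <- r
  }
  if (counts[["markov"]] > 0) {
    if (is.null(clusters)) {
      asg <- greedy_identity_cluster(ltrs, cluster_threshold)
      clusters <- asg$cluster[match(ltrs$id, asg$id)]
    }
    stopifnot(length(clusters) == nrow(ltrs))
    cl_ids <- split(seq_len(nrow(ltrs)), clusters)
    sizes <- lengths(cl_ids)
    per_cl <- allocate_counts(counts[["markov"]], sizes / sum(sizes))
    seqs_out <- character(counts[["markov"]])
    pos <- 0L
    for (ci in seq_along(cl_ids)) {
      if (per_cl[ci] == 0L) next
      sub <- ltrs[cl_ids[[ci]], ]
      model <- train_markov(sub, order = order, pseudocount = pseudocount)
      gl <- with_seed(derive_seed(seed, 100L + ci),
                      sample(model$lengths, per_cl[ci], replace = TRUE))
      for (j in seq_len(per_cl[ci])) {
        pos <- pos + 1L
        seqs_out[pos] <- generate_markov(model, gl[j],
                                         seed = derive_seed(seed, 1000L + pos))
      }
    }
    m <- sequence_tbl(sprintf("neg_markov_%04d", seq_len(counts[["markov"]])),
                      seqs_out, is_ltr = FALSE)
    m$neg_class <- "markov"
    pieces$markov <- m
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "class_counts") <- counts
  out
}
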