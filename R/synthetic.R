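# Synthetic LTR-like dataset generator: positives with superfamily-specific
# terminal tetramers, an internal TATA box at a configurable relative
# position, and family-specific planted PWM motif instances; negatives built
# by the negative-set recipes. Every planted element is recorded in a truth
# table, so signal recovery is measurable.

#' Specification of a synthetic LTR dataset
#'
#' Defaults encode the study conditions the toolkit is exercised under:
#' sequence lengths 300–3000 bp, canonical edge tetramers per superfamily
#' (Copia TGTT..AACA, Gypsy TGAT..ATCA), a TATAWA box at 45% of the length
#' (LTR promoters carry a centrally positioned TATA box), 15 families with 3
#' planted motifs each drawn from disjoint consensus pools, and negatives in
#' equal thirds of genomic-like, uniform-random and Markov-resampled
#' sequences.
#'
#' @param n_positive,n_negative Sequence counts.
#' @param families Named character vector mapping family name to superfamily;
#'   default: the 15 default families split between Ty1/Copia and Ty3/Gypsy.
#' @param length_range Min/max sequence length.
#' @param edges Named list mapping superfamily to `c(t5, t3)`.
#' @param tata_frac Relative TATA-box position.
#' @param motifs_per_family,motif_width,instances_per_motif Planted motif
#'   geometry.
#' @param consensus_prob Probability mass of the consensus base in a planted
#'   PWM at full signal strength.
#' @param signal_strength In [0, 1]: fidelity of the planted motif
#'   instances — 1 samples from the full-information PWMs, 0 from motifs
#'   indistinguishable from background.
#' @param neg_proportions Negative class mix (see [compose_negative_set()]).
#' @param seed Integer seed; regeneration under the same seed is
#'   byte-identical.
#' @return A list of class `ltr_synth_spec`.
#' @export
synthetic_spec <- function(n_positive = 2000L, n_negative = 2000L,
                           families = default_family_map(),
                           length_range = c(300L, 3000L),
                           edges = list("Ty1/Copia" = c("TGTT", "AACA"),
                                        "Ty3/Gypsy" = c("TGAT", "ATCA")),
                           tata_frac = 0.45, motifs_per_family = 3L,
                           motif_width = 12L, instances_per_motif = 2L,
                           consensus_prob = 0.95, signal_strength = 1,
                           neg_proportions = c(genomic = 1/3, random = 1/3,
                                               markov = 1/3),
                           seed = 1L) {
  stopifnot(length_range[1] <= length_range[2],
            is_scalar_fraction(signal_strength),
            is_scalar_fraction(tata_frac))
  if (motif_width + 20L > length_range[1]) {
    abort("motif width incompatible with the minimum sequence length")
  }
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 families = families, length_range = as.integer(length_range),
                 edges = edges, tata_frac = tata_frac,
                 motifs_per_family = as.integer(motifs_per_family),
                 motif_width = as.integer(motif_width),
                 instances_per_motif = as.integer(instances_per_motif),
                 consensus_prob = consensus_prob,
                 signal_strength = signal_strength,
                 neg_proportions = neg_proportions, seed = as.integer(seed)),
            class = "ltr_synth_spec")
}

#' Default family-to-superfamily map of the synthetic generator
#'
#' @return Named character vector (names = families, values = superfamily).
#' @export
default_family_map <- function() {
  c(Ale = "Ty1/Copia", Alesia = "Ty1/Copia", Angela = "Ty1/Copia",
    Bianca = "Ty1/Copia", Ikeros = "Ty1/Copia", Ivana = "Ty1/Copia",
    SIRE = "Ty1/Copia", TAR = "Ty1/Copia", Tork = "Ty1/Copia",
    Athila = "Ty3/Gypsy", CRM = "Ty3/Gypsy", Galadriel = "Ty3/Gypsy",
    Reina = "Ty3/Gypsy", Retand = "Ty3/Gypsy", Tekay = "Ty3/Gypsy")
}

# Disjoint family motif PWMs: consensus strings drawn without shared
# 6-mer content, interpolated toward the uniform background by strength.
synth_family_motifs <- function(spec) {
  fams <- names(spec$families)
  n_needed <- length(fams) * spec$motifs_per_family
  with_seed(derive_seed(spec$seed, 11L), {
    seen_kmers <- character(0)
    consensi <- character(0)
    while (length(consensi) < n_needed) {
      cand <- random_dna(spec$motif_width)
      kms <- distinct_kmers(cand, 6L)
      if (length(intersect(kms, seen_kmers)) == 0L) {
        consensi <- c(consensi, cand)
        seen_kmers <- c(seen_kmers, kms)
      }
    }
    out <- list()
    idx <- 0L
    p_major <- spec$consensus_prob
    p_minor <- (1 - p_major) / 3
    for (fam in fams) {
      for (mi in seq_len(spec$motifs_per_family)) {
        idx <- idx + 1L
        cons <- seq_to_codes(consensi[idx]) + 1L
        m <- matrix(p_minor, 4, spec$motif_width)
        m[cbind(cons, seq_len(spec$motif_width))] <- p_major
        out[[sprintf("%s_m%d", fam, mi)]] <-
          pwm_motif(sprintf("%s_m%d", fam, mi), m, "probabilities")
      }
    }
    out
  })
}

# Draw one motif instance; `strength` interpolates the PWM toward the
# uniform background (strength 0 = unrecognisable, 1 = full information).
# The square-root profile keeps intermediate strengths inside the sensitive
# range of a range-threshold scanner (a linear profile collapses the
# midpoint to near-background fidelity).
sample_from_pwm <- function(motif, strength = 1) {
  w <- sqrt(strength)
  q <- w * motif$matrix + (1 - w) * 0.25
  codes <- vapply(seq_len(motif$width), function(j) {
    sample.int(4L, 1L, prob = q[, j]) - 1L
  }, integer(1))
  codes_to_seq(codes)
}

# AT-rich plant-like order-2 background model used for the genomic-like
# negative class (CG-depleted, as plant intergenic sequence typically is).
synth_genome_model <- function() {
  contexts <- all_contexts(2L)
  base_p <- c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)
  trans <- matrix(rep(base_p, each = length(contexts)), ncol = 4,
                  dimnames = list(contexts, DNA_BASES))
  cg <- endsWith(contexts, "C")
  trans[cg, "G"] <- trans[cg, "G"] * 0.4
  trans <- trans / rowSums(trans)
  init <- setNames(rep(1 / length(contexts), length(contexts)), contexts)
  structure(list(transition = trans, initial = init, order = 2L,
                 pseudocount = 0, lengths = integer(0)),
            class = "ltr_markov")
}

#' Generate a synthetic LTR dataset
#'
#' Builds positives with planted, recoverable structure (edges, TATA box,
#' family motifs), negatives via the negative-set recipes (the Markov class
#' is trained on the positives grouped by family), and a truth table of
#' every planted coordinate (0-based half-open). Fully deterministic under
#' the spec seed.
#'
#' @param spec An [synthetic_spec()].
#' @return A list: `positives`, `negatives` (sequence tibbles), `truth`
#'   (tibble `seq_id`, `feature`, `name`, `start`, `end`), `motifs` (the
#'   planted family PWMs), `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "ltr_synth_spec"))
  fams <- names(spec$families)
  motifs <- synth_family_motifs(spec)
  truth <- list()
  if (spec$n_positive > 0L) {
    pos <- with_seed(derive_seed(spec$seed, 21L), {
      fam_of <- rep_len(fams, spec$n_positive)
      ids <- sprintf("ltr_%05d", seq_len(spec$n_positive))
      seqs <- character(spec$n_positive)
      for (i in seq_len(spec$n_positive)) {
        fam <- fam_of[i]
        sf <- spec$families[[fam]]
        edge <- spec$edges[[sf]]
        L <- sample(spec$length_range[1]:spec$length_range[2], 1L)
        body <- sample.int(4L, L, replace = TRUE) - 1L
        s <- codes_to_seq(body)
        occupied <- matrix(c(0L, 4L, L - 4L, L), ncol = 2, byrow = TRUE)
        place <- function(s, piece, start) {
          paste0(substr(s, 1, start), piece,
                 substr(s, start + nchar(piece) + 1L, nchar(s)))
        }
        # TATA box
        tata_start <- as.integer(floor(spec$tata_frac * L))
        tata_seq <- paste0("TATA", sample(c("A", "T"), 1L), "A")
        s <- place(s, tata_seq, tata_start)
        occupied <- rbind(occupied, c(tata_start, tata_start + 6L))
        truth[[length(truth) + 1L]] <- tibble(
          seq_id = ids[i], feature = "tata", name = tata_seq,
          start = tata_start, end = tata_start + 6L)
        # family motifs
        for (mi in seq_len(spec$motifs_per_family)) {
          mot <- motifs[[sprintf("%s_m%d", fam, mi)]]
          for (inst in seq_len(spec$instances_per_motif)) {
            w <- mot$width
            for (try in 1:60) {
              st <- sample(5:(L - w - 5L), 1L)
              if (!any(st < occupied[, 2] & occupied[, 1] < st + w)) break
            }
            piece <- sample_from_pwm(mot, spec$signal_strength)
            s <- place(s, piece, st)
            occupied <- rbind(occupied, c(st, st + w))
            truth[[length(truth) + 1L]] <- tibble(
              seq_id = ids[i], feature = "motif", name = mot$name,
              start = st, end = st + w)
          }
        }
        # terminal tetramers
        s <- paste0(edge[1], substr(s, 5, L - 4L), edge[2])
        truth[[length(truth) + 1L]] <- tibble(
          seq_id = ids[i], feature = "edge5", name = edge[1],
          start = 0L, end = 4L)
        truth[[length(truth) + 1L]] <- tibble(
          seq_id = ids[i], feature = "edge3", name = edge[2],
          start = L - 4L, end = L)
        seqs[i] <- s
      }
      sequence_tbl(ids, seqs, species = "synthetic", is_ltr = TRUE,
                   superfamily = unname(spec$families[fam_of]),
                   family = fam_of)
    })
  } else {
    pos <- sequence_tbl(character(0), character(0))[0, ]
  }

  if (spec$n_negative > 0L) {
    if (spec$n_positive == 0L) {
      abort("negatives need positives to train the Markov class on")
    }
    genome <- with_seed(derive_seed(spec$seed, 31L), {
      gm <- synth_genome_model()
      contig_len <- max(100000L, spec$length_range[2] * 40L)
      sequence_tbl(c("contig_1", "contig_2"),
                   c(generate_markov(gm, contig_len),
                     generate_markov(gm, contig_len)))
    })
    neg <- compose_negative_set(
      pos, genome_seqs = genome, proportions = spec$neg_proportions,
      n_total = spec$n_negative, seed = derive_seed(spec$seed, 41L),
      clusters = pos$family)
  } else {
    neg <- sequence_tbl(character(0), character(0))[0, ]
  }
  list(positives = pos, negatives = neg,
       truth = if (length(truth)) dplyr::bind_rows(truth) else
         tibble(seq_id = character(0), feature = character(0),
                name = character(0), start = integer(0), end = integer(0)),
       motifs = motifs, spec = spec)
}

#' Generate datasets across a signal-strength sweep
#'
#' One dataset per strength, identical otherwise (same seed): planted-motif
#' information content is interpolated between the uniform background
#' (strength 0) and the full-information PWMs (strength 1).
#'
#' @param spec An [synthetic_spec()].
#' @param signal_strengths Numeric vector in [0, 1].
#' @return A named list of [generate_dataset()] results.
#' @export
difficulty_sweep <- function(spec, signal_strengths = c(0, 0.5, 1)) {
  stopifnot(all(signal_strengths >= 0 & signal_strengths <= 1))
  out <- lapply(signal_strengths, function(s) {
    sp <- spec
    sp$signal_strength <- s
    generate_dataset(sp)
  })
  names(out) <- sprintf("strength_%g", signal_strengths)
  out
}
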