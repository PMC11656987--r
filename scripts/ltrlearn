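#!/usr/bin/env Rscript

# Thin command-line front end over the ltrlearn package:
#   ltrlearn synth     --out DIR [--n-positive N] [--n-negative N] [--seed S]
#   ltrlearn featurize --fasta F --motifs JASPAR --out TSV [--rel-threshold X]
#   ltrlearn train     --features TSV --labels TSV --task ltr --out RDS
#   ltrlearn evaluate  --model RDS --features TSV --labels TSV --out TSV
#   ltrlearn edges     --fasta F --out TSV [--top-n N]
# Every command is a direct composition of exported package functions; use
# the package interactively for anything beyond these pipelines.

suppressMessages({
  library(optparse)
  library(ltrlearn)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0L) {
  stop("usage: ltrlearn <synth|featurize|train|evaluate|edges> [options]")
}
command <- args[[1]]
rest <- args[-1]

read_labels <- function(path, ids) {
  lab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lab[[2]][match(ids, lab[[1]])]
}

run <- switch(
  command,
  synth = function() {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--out", type = "character"),
      make_option("--n-positive", type = "integer", default = 2000L,
                  dest = "n_positive"),
      make_option("--n-negative", type = "integer", default = 2000L,
                  dest = "n_negative"),
      make_option("--seed", type = "integer", default = 1L))), args = rest)
    dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
    ds <- generate_dataset(synthetic_spec(n_positive = o$n_positive,
                                          n_negative = o$n_negative,
                                          seed = o$seed))
    write_fasta(ds$positives, file.path(o$out, "positives.fa"),
                header_scheme = "id|species|superfamily|family|is_ltr")
    write_fasta(ds$negatives, file.path(o$out, "negatives.fa"),
                header_scheme = "id|species|superfamily|family|is_ltr")
    utils::write.table(ds$truth, file.path(o$out, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_jaspar_pfm(lapply(ds$motifs, function(m) {
      pwm_motif(m$name, round(m$matrix * 1000), "counts")
    }), file.path(o$out, "motifs.pfm"))
    message(sprintf("wrote %d positives / %d negatives to %s",
                    nrow(ds$positives), nrow(ds$negatives), o$out))
  },
  featurize = function() {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--fasta", type = "character"),
      make_option("--motifs", type = "character"),
      make_option("--out", type = "character"),
      make_option("--rel-threshold", type = "double", default = 0.8,
                  dest = "rel_threshold"),
      make_option("--tfidf", action = "store_true", default = FALSE))),
      args = rest)
    seqs <- read_fasta(o$fasta)
    mots <- read_jaspar_pfm(o$motifs)
    fm <- scan_pwm_counts(seqs, mots, rel_threshold = o$rel_threshold)
    if (o$tfidf) fm <- tfidf_transform(fm)
    utils::write.table(fm, o$out, sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("wrote %d x %d feature table to %s",
                    nrow(fm), ncol(fm) - 1L, o$out))
  },
  train = function() {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--features", type = "character"),
      make_option("--labels", type = "character"),
      make_option("--out", type = "character"),
      make_option("--nrounds", type = "integer", default = 150L),
      make_option("--max-depth", type = "integer", default = 3L,
                  dest = "max_depth"),
      make_option("--seed", type = "integer", default = 1L))), args = rest)
    fm <- tibble::as_tibble(utils::read.delim(o$features,
                                              stringsAsFactors = FALSE))
    attr(fm, "kind") <- "counts"
    fm_t <- tfidf_transform(fm)
    labels <- read_labels(o$labels, fm$seq_id)
    fit <- train_gbdt(fm_t, as.logical(labels),
                      hyperparams = list(nrounds = o$nrounds,
                                         max_depth = o$max_depth),
                      seed = o$seed)
    saveRDS(list(fit = fit, idf = attr(fm_t, "idf")), o$out)
    message(sprintf("model written to %s", o$out))
  },
  evaluate = function() {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--model", type = "character"),
      make_option("--features", type = "character"),
      make_option("--labels", type = "character"),
      make_option("--out", type = "character"))), args = rest)
    st <- readRDS(o$model)
    fm <- tibble::as_tibble(utils::read.delim(o$features,
                                              stringsAsFactors = FALSE))
    attr(fm, "kind") <- "counts"
    fm_t <- tfidf_transform(fm, idf = st$idf)
    labels <- as.logical(read_labels(o$labels, fm$seq_id))
    pred <- predict(st$fit, fm_t)
    rep <- compute_metrics(as.character(labels), pred, averaging = "binary",
                           positive = "TRUE")
    out <- dplyr::bind_rows(glance(rep) |> dplyr::mutate(class = "(overall)"),
                            tidy(rep))
    utils::write.table(out, o$out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message(sprintf("precision %.3f recall %.3f F1 %.3f",
                    rep$precision, rep$recall, rep$f1))
  },
  edges = function() {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--fasta", type = "character"),
      make_option("--out", type = "character"),
      make_option("--top-n", type = "integer", default = 5L,
                  dest = "top_n"))), args = rest)
    seqs <- read_fasta(o$fasta)
    sm <- summarize_edges(edge_tetramers(seqs), top_n = o$top_n)
    utils::write.table(as.data.frame(sm), o$out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message(sprintf("edge summary (top %d pairs) written to %s", o$top_n,
                    o$out))
  },
  stop(sprintf("unknown command '%s'", command))
)
run()
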