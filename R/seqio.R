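# Sequence and motif IO: FASTA with labelled headers, JASPAR PFMs, MEME
# minimal format. Sequences travel as tibbles (one row per record); motifs as
# `ltr_pwm` objects collected in plain lists.

#' Construct a labelled sequence table
#'
#' The canonical tabular container used throughout the package: one row per
#' DNA sequence with optional task labels. The family label implies a
#' superfamily label (families are lineages within a superfamily).
#'
#' @param id Character vector of unique sequence identifiers.
#' @param sequence Character vector of DNA sequences over A/C/G/T/N
#'   (lower case and U are normalised).
#' @param species,superfamily,family Optional character label vectors.
#' @param is_ltr Optional logical vector (positive/negative class).
#' @return A tibble with columns `id`, `sequence`, `species`, `is_ltr`,
#'   `superfamily`, `family`.
#' @export
#' @examples
#' sequence_tbl("s1", "TGTTACGTAACA", is_ltr = TRUE, superfamily = "Ty1/Copia")
sequence_tbl <- function(id, sequence, species = NA_character_, is_ltr = NA,
                         superfamily = NA_character_, family = NA_character_) {
  sequence <- vapply(sequence, normalize_sequence, character(1), USE.NAMES = FALSE)
  if (any(nchar(sequence) == 0L)) abort("sequences must be non-empty")
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    abort(sprintf("sequence %s contains characters outside A/C/G/T/N",
                  id[which(bad)[1]]))
  }
  out <- tibble(
    id = as.character(id),
    sequence = sequence,
    species = as.character(species),
    is_ltr = as.logical(is_ltr),
    superfamily = as.character(superfamily),
    family = as.character(family)
  )
  if (any(!is.na(out$family) & is.na(out$superfamily))) {
    abort("a family label requires a superfamily label")
  }
  out
}

parse_fasta_header <- function(headers, header_scheme) {
  fields <- strsplit(header_scheme, "|", fixed = TRUE)[[1]]
  parts <- strsplit(headers, "|", fixed = TRUE)
  out <- lapply(seq_along(fields), function(i) {
    vapply(parts, function(p) {
      v <- if (length(p) >= i) trimws(p[[i]]) else NA_character_
      if (is.na(v) || v == "" || v == "NA") NA_character_ else v
    }, character(1))
  })
  names(out) <- fields
  out
}

#' Read a labelled FASTA file
#'
#' Reads FASTA records and parses task labels from the header under a
#' configurable scheme (fields separated by `|`). Unparseable fields are left
#' `NA`; sequences are upper-cased. The default scheme is
#' `"id|species|superfamily|family"`.
#'
#' @param path Path to a FASTA file.
#' @param header_scheme Pipe-separated field names; recognised names are
#'   `id`, `species`, `superfamily`, `family`, `is_ltr`.
#' @return A sequence tibble (see [sequence_tbl()]).
#' @export
read_fasta <- function(path, header_scheme = "id|species|superfamily|family") {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("empty FASTA file: %s", path))
  if (!startsWith(lines[[1]], ">")) {
    abort(sprintf("malformed FASTA at line 1 of %s: expected '>'", path))
  }
  hdr_idx <- which(startsWith(lines, ">"))
  starts <- hdr_idx + 1L
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  if (any(starts > ends)) {
    i <- which(starts > ends)[1]
    abort(sprintf("malformed FASTA: record at line %d of %s has no sequence",
                  hdr_idx[i], path))
  }
  headers <- sub("^>", "", lines[hdr_idx])
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  lab <- parse_fasta_header(headers, header_scheme)
  get_field <- function(nm, default) if (!is.null(lab[[nm]])) lab[[nm]] else default
  ids <- get_field("id", headers)
  ids[is.na(ids)] <- headers[is.na(ids)]
  fam <- get_field("family", NA_character_)
  sf <- get_field("superfamily", NA_character_)
  # an orphan family label (no parsable superfamily) is treated as unparsed
  fam[!is.na(fam) & is.na(sf)] <- NA_character_
  is_ltr <- get_field("is_ltr", NA_character_)
  sequence_tbl(
    id = ids, sequence = seqs,
    species = get_field("species", NA_character_),
    is_ltr = if (is.character(is_ltr)) as.logical(is_ltr) else is_ltr,
    superfamily = sf, family = fam
  )
}

#' Write a labelled FASTA file
#'
#' Inverse of [read_fasta()]: headers are rebuilt from the label columns under
#' the same scheme, `NA` fields rendered as `NA` placeholders so round-trips
#' preserve labels.
#'
#' @param seqs A sequence tibble.
#' @param path Output path.
#' @param header_scheme Same contract as in [read_fasta()].
#' @param width Line-wrap width for sequence text.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, header_scheme = "id|species|superfamily|family",
                        width = 70L) {
  assert_sequence_tbl(seqs)
  fields <- strsplit(header_scheme, "|", fixed = TRUE)[[1]]
  hdr <- vapply(seq_len(nrow(seqs)), function(i) {
    vals <- vapply(fields, function(f) {
      v <- if (f %in% names(seqs)) seqs[[f]][[i]] else NA
      if (is.na(v)) "NA" else as.character(v)
    }, character(1))
    paste(vals, collapse = "|")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", hdr[i]), con)
    s <- seqs$sequence[[i]]
    L <- nchar(s)
    writeLines(substring(s, seq(1L, L, width), pmin(seq(width, L + width - 1L, width), L)), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# PWM objects

#' Construct a position weight/frequency matrix object
#'
#' @param name Motif name.
#' @param matrix A 4 x width numeric matrix, rows A, C, G, T; counts or
#'   probabilities according to `kind`.
#' @param kind `"counts"` (non-negative, at least one positive entry per
#'   column) or `"probabilities"` (columns sum to 1 within 1e-6).
#' @return An object of class `ltr_pwm`.
#' @export
pwm_motif <- function(name, matrix, kind = c("counts", "probabilities")) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) abort("PWM must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 1L) abort("PWM must have positive width")
  if (any(matrix < 0)) abort(sprintf("motif %s: negative entries", name))
  if (kind == "counts") {
    if (any(colSums(matrix) <= 0)) {
      abort(sprintf("motif %s: every column needs a positive count", name))
    }
  } else {
    if (any(abs(colSums(matrix) - 1) > 1e-6)) {
      abort(sprintf("motif %s: probability columns must sum to 1", name))
    }
  }
  rownames(matrix) <- DNA_BASES
  structure(list(name = name, matrix = matrix, kind = kind,
                 width = ncol(matrix)),
            class = "ltr_pwm")
}

#' @export
print.ltr_pwm <- function(x, ...) {
  cat(sprintf("<ltr_pwm> %s (%s, width %d)\n", x$name, x$kind, x$width))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Convert a count motif to probabilities
#'
#' @param motif An `ltr_pwm`.
#' @param pseudocount Added to every cell before column normalisation.
#' @return An `ltr_pwm` with `kind = "probabilities"`.
#' @export
to_probabilities <- function(motif, pseudocount = 0) {
  stopifnot(inherits(motif, "ltr_pwm"))
  if (motif$kind == "probabilities" && pseudocount == 0) return(motif)
  m <- motif$matrix + pseudocount
  m <- sweep(m, 2, colSums(m), "/")
  pwm_motif(motif$name, m, "probabilities")
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR PFM text dialects: a `>name` line followed by four rows of
#' counts in A, C, G, T order, either bare numbers or the bracketed
#' `A [ 4 19 0 ]` layout.
#'
#' @param path Path to a JASPAR PFM file.
#' @return A list of `ltr_pwm` objects with `kind = "counts"`.
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) abort(sprintf("JASPAR file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- which(startsWith(trimws(lines), ">"))
  if (length(hdr_idx) == 0L) abort(sprintf("no motifs found in %s", path))
  motifs <- vector("list", length(hdr_idx))
  bounds <- c(hdr_idx[-1], length(lines) + 1L)
  for (i in seq_along(hdr_idx)) {
    name <- trimws(sub("^\\s*>\\s*", "", lines[hdr_idx[i]]))
    body <- lines[seq(hdr_idx[i] + 1L, bounds[i] - 1L)]
    if (length(body) != 4L) {
      abort(sprintf("motif %s: expected 4 count rows, found %d", name, length(body)))
    }
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ \t]*[ACGTacgt][ \t:|]*", "", ln)
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]]))
      if (any(is.na(vals)) || length(vals) == 0L) {
        abort(sprintf("motif %s: unparseable count row '%s'", name, ln))
      }
      vals
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      abort(sprintf("motif %s: row lengths differ (%s)", name,
                    paste(widths, collapse = ", ")))
    }
    m <- do.call(rbind, rows)
    if (any(m < 0)) abort(sprintf("motif %s: negative count", name))
    motifs[[i]] <- pwm_motif(name, m, "counts")
  }
  motifs
}

#' Write motifs in JASPAR PFM format
#'
#' @param motifs List of `ltr_pwm` count motifs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    stopifnot(inherits(m, "ltr_pwm"))
    writeLines(paste0(">", m$name), con)
    for (b in 1:4) {
      writeLines(sprintf("%s  [ %s ]", DNA_BASES[b],
                         paste(format(m$matrix[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write motifs in MEME minimal format (version 4)
#'
#' Emits the minimal motif format understood by the MEME suite: a version
#' line, `ALPHABET= ACGT`, a background frequency line, and one
#' letter-probability matrix block per motif. Motifs must already be in
#' probability form (see [to_probabilities()]).
#'
#' @param motifs List of `ltr_pwm` probability motifs.
#' @param path Optional output path; when `NULL` the text is returned.
#' @param background Background probabilities for A, C, G, T.
#' @param nsites `nsites` field written per motif.
#' @return The MEME text, invisibly when written to `path`.
#' @export
write_meme <- function(motifs, path = NULL, background = rep(0.25, 4),
                       nsites = 20L) {
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  for (m in motifs) {
    stopifnot(inherits(m, "ltr_pwm"))
    if (m$kind != "probabilities") {
      abort(sprintf(
        "motif %s is in counts form; call to_probabilities() before write_meme()",
        m$name))
    }
  }
  out <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", background[1], background[2],
            background[3], background[4]), ""
  )
  for (m in motifs) {
    out <- c(out,
             sprintf("MOTIF %s", m$name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                     m$width, nsites),
             vapply(seq_len(m$width), function(j) {
               paste(sprintf("%.6f", m$matrix[, j]), collapse = " ")
             }, character(1)),
             "")
  }
  text <- paste(out, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(out, path)
  invisible(text)
}

#' Read MEME minimal format motifs
#'
#' Companion reader for [write_meme()] output (and other minimal-format MEME
#' files restricted to the ACGT alphabet).
#'
#' @param path Path to a MEME minimal-format file.
#' @return A list of `ltr_pwm` probability motifs.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  motif_idx <- which(startsWith(trimws(lines), "MOTIF"))
  motifs <- list()
  for (i in seq_along(motif_idx)) {
    name <- trimws(sub("^\\s*MOTIF\\s+", "", lines[motif_idx[i]]))
    name <- strsplit(name, "\\s+")[[1]][1]
    j <- motif_idx[i] + 1L
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) abort(sprintf("motif %s: missing letter-probability matrix", name))
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1L):(j + w)]
    m <- vapply(rows, function(ln) {
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    }, numeric(4)) # 4 x w
    sums <- colSums(m)
    if (any(abs(sums - 1) > 1e-4)) {
      abort(sprintf("motif %s: probability rows do not sum to 1", name))
    }
    m <- sweep(m, 2, sums, "/") # absorb fixed-precision rounding drift
    motifs[[length(motifs) + 1L]] <- pwm_motif(name, m, "probabilities")
  }
  motifs
}
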