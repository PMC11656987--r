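# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library functions never clobber user state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed, staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587)
}

#' Reverse-complement a DNA string
#'
#' Plain-string reverse complement over the A/C/G/T alphabet (N maps to N).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TGTT") # "AACA"
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Map a DNA string to integer codes A=0 C=1 G=2 T=3, N/other = NA.
seq_to_codes <- function(s) {
  raw_codes <- utf8ToInt(s)
  out <- rep(NA_integer_, length(raw_codes))
  out[raw_codes == 65L] <- 0L # A
  out[raw_codes == 67L] <- 1L # C
  out[raw_codes == 71L] <- 2L # G
  out[raw_codes == 84L] <- 3L # T
  out
}

codes_to_seq <- function(codes) {
  paste(DNA_BASES[codes + 1L], collapse = "")
}

# Normalise raw sequence text: upper case, RNA U -> T.
normalize_sequence <- function(s) {
  chartr("u", "T", chartr("acgtn", "ACGTN", toupper(s)))
}

assert_sequence_tbl <- function(seqs, arg = "seqs") {
  if (!is.data.frame(seqs) || !all(c("id", "sequence") %in% names(seqs))) {
    abort(sprintf("`%s` must be a data frame with at least `id` and `sequence` columns", arg))
  }
  invisible(seqs)
}

# Distinct k-mers of one string (character vector, possibly empty).
distinct_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  unique(substring(s, 1:(L - k + 1L), k:L))
}

is_scalar_fraction <- function(x, lo = 0, hi = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo && x <= hi
}
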