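# Metrics and model-comparison statistics: precision/recall/F1 reports,
# stratified k-fold assignment, the Wilcoxon signed-rank test (exact,
# tie-aware null distribution), and the Friedman test with Nemenyi post-hoc
# analysis.

#' Precision, recall and F1
#'
#' Binary averaging scores the configured positive class; multiclass
#' averaging computes one-vs-rest per-class scores and combines them
#' support-weighted (`"weighted"`) or unweighted (`"macro"`). Undefined
#' ratios (no predicted or no true instances of a class) count as 0.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param averaging `"binary"`, `"weighted"` or `"macro"`.
#' @param positive Positive class for binary averaging (default: `TRUE`,
#'   `1`, or the lexicographically last level).
#' @return A one-row tibble `precision`, `recall`, `f1`, `averaging` of class
#'   `ltr_metrics`; the per-class table is in attribute `per_class` (also
#'   available via [tidy()]).
#' @export
compute_metrics <- function(y_true, y_pred,
                            averaging = c("binary", "weighted", "macro"),
                            positive = NULL) {
  averaging <- match.arg(averaging)
  if (length(y_true) == 0L) abort("empty input")
  if (length(y_true) != length(y_pred)) abort("length mismatch")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  per <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    tibble(class = cl, precision = p, recall = r, f1 = f,
           support = sum(y_true == cl))
  })
  per <- dplyr::bind_rows(per)
  if (averaging == "binary") {
    if (is.null(positive)) {
      positive <- if ("TRUE" %in% classes) "TRUE" else utils::tail(classes, 1)
    }
    row <- per[per$class == as.character(positive), ]
    if (nrow(row) == 0L) abort(sprintf("positive class '%s' absent", positive))
    out <- tibble(precision = row$precision, recall = row$recall, f1 = row$f1,
                  averaging = "binary")
  } else {
    wts <- if (averaging == "weighted") per$support else rep(1, nrow(per))
    wts <- wts / sum(wts)
    out <- tibble(precision = sum(per$precision * wts),
                  recall = sum(per$recall * wts),
                  f1 = sum(per$f1 * wts),
                  averaging = averaging)
  }
  attr(out, "per_class") <- per
  class(out) <- c("ltr_metrics", class(out))
  out
}

#' @method tidy ltr_metrics
#' @export
tidy.ltr_metrics <- function(x, ...) attr(x, "per_class")

#' @method glance ltr_metrics
#' @export
glance.ltr_metrics <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ltr_metrics")
  attr(out, "per_class") <- NULL
  out
}

#' Stratified k-fold assignment
#'
#' Partitions indices into `k` folds so that each fold's class proportions
#' deviate from the global ones by at most one item per class.
#'
#' @param labels Label vector.
#' @param k Number of folds (at most the smallest class size).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per label.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  min_class <- min(table(labels))
  if (k > min_class) {
    abort(sprintf("k = %d exceeds the smallest class size (%d)", k, min_class))
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Exact null distribution of the sum of signed ranks, tie-aware: dynamic
# programming over doubled ranks (integers even with midranks).
signed_rank_null_cdf <- function(ranks2) {
  total <- sum(ranks2)
  probs <- numeric(total + 1)
  probs[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs[seq_len(total + 1 - r)])
    probs <- (probs + shifted) / 2
  }
  probs # probs[v+1] = P(2*Vplus == v)
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Two-sided test on paired differences; zero differences are dropped
#' (Wilcoxon convention) and ties receive average ranks. The p-value uses the
#' exact (tie-aware) null distribution of the signed-rank sum for n <= 25 and
#' the tie-corrected normal approximation above.
#'
#' @param paired_a,paired_b Equal-length numeric score vectors.
#' @return A one-row tibble: `statistic` (the smaller of the positive and
#'   negative rank sums), `p_value`, `n` (non-zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  stopifnot(length(paired_a) == length(paired_b))
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort("all paired differences are zero")
  if (n < 5L) warn("fewer than 5 non-zero differences; the test has little power")
  r <- rank(abs(d))
  v_plus <- sum(r[d > 0])
  v_minus <- sum(r[d < 0])
  stat <- min(v_plus, v_minus)
  if (n <= 25L) {
    cdf <- signed_rank_null_cdf(as.integer(round(2 * r)))
    v2 <- as.integer(round(2 * v_plus))
    p_lo <- sum(cdf[seq_len(v2 + 1)])
    p_hi <- sum(cdf[(v2 + 1):length(cdf)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v_plus - mu - sign(v_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  tibble(statistic = stat, p_value = p, n = n, method = method)
}

#' Friedman test with Nemenyi post-hoc comparison
#'
#' The Friedman chi-square is computed on within-row ranks (average ranks on
#' ties): `chi2 = 12k / (m(m+1)) * sum_j (Rbar_j - (m+1)/2)^2` over `m`
#' models scored on `k` datasets. When the Friedman test rejects at `alpha`,
#' pairwise Nemenyi p-values are derived from the studentized-range
#' distribution of mean-rank differences.
#'
#' @param score_matrix Numeric matrix, k datasets (rows) x m models
#'   (columns), m >= 3.
#' @param alpha Gate for running the Nemenyi analysis.
#' @return A list: `friedman` (one-row tibble `statistic`, `df`, `p_value`),
#'   `mean_ranks`, and `nemenyi` (symmetric p-value matrix with unit
#'   diagonal, or `NULL` when the Friedman test does not reject).
#' @export
friedman_nemenyi <- function(score_matrix, alpha = 0.05) {
  score_matrix <- as.matrix(score_matrix)
  k <- nrow(score_matrix)
  m <- ncol(score_matrix)
  if (m < 3L || k < 2L) abort("need at least 3 models and 2 datasets")
  if (all(apply(score_matrix, 1, function(x) length(unique(x)) == 1L))) {
    abort("every row is constant; ranks are degenerate")
  }
  ranks <- t(apply(score_matrix, 1, rank))
  rbar <- colMeans(ranks)
  stat <- 12 * k / (m * (m + 1)) * sum((rbar - (m + 1) / 2)^2)
  p <- stats::pchisq(stat, df = m - 1, lower.tail = FALSE)
  nemenyi <- NULL
  if (p <= alpha) {
    se <- sqrt(m * (m + 1) / (6 * k))
    nemenyi <- matrix(1, m, m, dimnames = list(colnames(score_matrix),
                                               colnames(score_matrix)))
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- abs(rbar[i] - rbar[j]) / se * sqrt(2)
        pv <- stats::ptukey(q, nmeans = m, df = Inf, lower.tail = FALSE)
        nemenyi[i, j] <- pv
        nemenyi[j, i] <- pv
      }
    }
  }
  list(friedman = tibble(statistic = stat, df = m - 1, p_value = p),
       mean_ranks = rbar, nemenyi = nemenyi)
}
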