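# Windowed-embedding pooling track: any fixed-dimension sequence embedder
# (the contract a transformer encoder satisfies) is slid along the sequence
# in 510-base windows with stride 170, the window embeddings are
# average-pooled, and a small convolutional head (32 filters of size 3 over
# the pooled vector, dense 32, task output) is trained on the pooled vectors.

#' Average-pooled windowed embeddings of one sequence
#'
#' Windows start at 0 and advance by `stride`; a final window anchored at the
#' sequence end is added when the last stride-aligned window does not reach
#' it. Sequences no longer than `window` produce a single embedder call.
#'
#' @param sequence A DNA string.
#' @param embedder Function mapping a sequence of length <= `window` to a
#'   fixed-length numeric vector.
#' @param window Window size (default 510, a transformer input length).
#' @param stride Window stride (default 170, one third of the window).
#' @return The element-wise mean of the window embeddings.
#' @export
window_pool_embeddings <- function(sequence, embedder, window = 510L,
                                   stride = 170L) {
  stopifnot(window > 0, stride > 0)
  s <- normalize_sequence(sequence)
  L <- nchar(s)
  if (L <= window) {
    starts <- 0L
  } else {
    starts <- seq(0L, L - window, by = stride)
    if (max(starts) + window < L) starts <- c(starts, L - window)
  }
  emb <- lapply(starts, function(st) {
    v <- embedder(substr(s, st + 1L, min(L, st + window)))
    as.numeric(v)
  })
  dims <- lengths(emb)
  if (length(unique(dims)) != 1L) {
    abort("embedder returned vectors of varying dimension")
  }
  Reduce(`+`, emb) / length(emb)
}

#' Deterministic k-mer-hash embedder
#'
#' The default offline embedder for the pooling track: k-mer counts hashed
#' into `dim` buckets (polynomial base-4 code modulo `dim`), L2-normalised.
#' Sequences with similar k-mer content map to nearby directions, which is
#' the property the pooled head exploits.
#'
#' @param dim Embedding dimension (default 768, a BERT-sized vector).
#' @param k k-mer length.
#' @return A function `sequence -> numeric[dim]`.
#' @export
kmer_hash_embedder <- function(dim = 768L, k = 6L) {
  force(dim); force(k)
  function(sequence) {
    cd <- seq_to_codes(normalize_sequence(sequence))
    cd <- cd[!is.na(cd)]
    out <- numeric(dim)
    L <- length(cd)
    if (L >= k) {
      # rolling polynomial code of each k-mer
      code <- 0
      pow <- 4^(k - 1)
      for (j in seq_len(k)) code <- code * 4 + cd[j]
      out[(code %% dim) + 1] <- out[(code %% dim) + 1] + 1
      if (L > k) {
        for (t in (k + 1):L) {
          code <- (code - cd[t - k] * pow) * 4 + cd[t]
          out[(code %% dim) + 1] <- out[(code %% dim) + 1] + 1
        }
      }
    }
    nrm <- sqrt(sum(out^2))
    if (nrm > 0) out <- out / nrm
    out
  }
}

#' Embed a sequence table with windowed pooling
#'
#' @param seqs A sequence tibble.
#' @param embedder See [window_pool_embeddings()].
#' @param window,stride Window geometry.
#' @return Numeric matrix, one pooled embedding row per sequence.
#' @export
pooled_embedding_matrix <- function(seqs, embedder = kmer_hash_embedder(),
                                    window = 510L, stride = 170L) {
  assert_sequence_tbl(seqs)
  rows <- lapply(seqs$sequence, window_pool_embeddings, embedder = embedder,
                 window = window, stride = stride)
  out <- do.call(rbind, rows)
  rownames(out) <- seqs$id
  out
}

#' Build the pooled-embedding classification head
#'
#' A 1-D convolution (32 filters of size 3) over the pooled embedding
#' vector, global max pooling, a dense layer of size 32, and the task output
#' (sigmoid for binary tasks, softmax for the family task).
#'
#' @param input_dim Embedding dimension (>= 3).
#' @param task Task name as in [build_cnn_lstm()].
#' @param class_names Optional class names.
#' @param n_filters,filter_width,dense_units Head topology.
#' @param seed Seed for initialisation.
#' @return A handle of class `ltr_pooled_head`.
#' @export
build_pooled_head <- function(input_dim, task = c("ltr_detection",
                                                  "superfamily", "family"),
                              class_names = NULL, n_filters = 32L,
                              filter_width = 3L, dense_units = 32L,
                              seed = 1L) {
  task <- match.arg(task)
  stopifnot(input_dim >= filter_width)
  if (is.null(class_names)) {
    class_names <- switch(task,
                          ltr_detection = c("FALSE", "TRUE"),
                          superfamily = c("Ty1/Copia", "Ty3/Gypsy"),
                          family = ltr_family_names())
  }
  K <- if (task == "family") length(class_names) else 1L
  params <- with_seed(seed, list(
    conv_W = glorot(filter_width, n_filters), conv_b = rep(0, n_filters),
    W1 = glorot(n_filters, dense_units), b1 = rep(0, dense_units),
    W_out = glorot(dense_units, K), b_out = rep(0, K)))
  structure(list(kind = "pooled_head", task = task, params = params,
                 config = list(input_dim = as.integer(input_dim),
                               n_filters = as.integer(n_filters),
                               filter_width = as.integer(filter_width),
                               dense_units = as.integer(dense_units)),
                 class_names = class_names, seed = as.integer(seed),
                 fitted = FALSE, history = NULL),
            class = "ltr_pooled_head")
}

# Forward pass of the pooled head; returns intermediates for the backward
# pass when `cache = TRUE`.
pooled_forward <- function(params, X, cfg, cache = FALSE) {
  B <- nrow(X)
  D <- ncol(X)
  wf <- cfg$filter_width
  Tt <- D - wf + 1L
  Fn <- cfg$n_filters
  Xim <- matrix(0, B * Tt, wf)
  for (j in seq_len(wf)) Xim[, j] <- as.vector(X[, j:(j + Tt - 1L)])
  Z <- sweep(Xim %*% params$conv_W, 2, params$conv_b, "+")
  A <- pmax(Z, 0)
  P <- matrix(0, B, Fn)
  amax <- matrix(0L, B, Fn)
  for (f in seq_len(Fn)) {
    Af <- matrix(A[, f], B, Tt)
    am <- max.col(Af, ties.method = "first")
    amax[, f] <- am
    P[, f] <- Af[cbind(seq_len(B), am)]
  }
  H1pre <- sweep(P %*% params$W1, 2, params$b1, "+")
  H1 <- pmax(H1pre, 0)
  logits <- sweep(H1 %*% params$W_out, 2, params$b_out, "+")
  if (!cache) return(list(logits = logits))
  list(logits = logits, Xim = Xim, Z = Z, P = P, amax = amax,
       H1pre = H1pre, H1 = H1, B = B, Tt = Tt)
}

pooled_loss_grad <- function(params, X, y, w, binary, cfg) {
  fw <- pooled_forward(params, X, cfg, cache = TRUE)
  B <- fw$B
  wsum <- sum(w)
  if (binary) {
    z <- fw$logits[, 1]
    loss <- sum(w * (pmax(z, 0) - z * y + log1p(exp(-abs(z))))) / wsum
    dlogits <- matrix(w * (1 / (1 + exp(-z)) - y) / wsum, ncol = 1)
  } else {
    zm <- fw$logits - apply(fw$logits, 1, max)
    p <- exp(zm) / rowSums(exp(zm))
    loss <- -sum(w * log(p[cbind(seq_len(B), y + 1L)])) / wsum
    dlogits <- p * (w / wsum)
    dlogits[cbind(seq_len(B), y + 1L)] <-
      dlogits[cbind(seq_len(B), y + 1L)] - w / wsum
  }
  dW_out <- t(fw$H1) %*% dlogits
  db_out <- colSums(dlogits)
  dH1 <- (dlogits %*% t(params$W_out)) * (fw$H1pre > 0)
  dW1 <- t(fw$P) %*% dH1
  db1 <- colSums(dH1)
  dP <- dH1 %*% t(params$W1)
  Fn <- cfg$n_filters
  dconv_W <- matrix(0, cfg$filter_width, Fn)
  dconv_b <- numeric(Fn)
  for (f in seq_len(Fn)) {
    sel <- (fw$amax[, f] - 1L) * B + seq_len(B)  # flat rows of Xim
    mask <- fw$Z[sel, f] > 0
    g <- dP[, f] * mask
    dconv_W[, f] <- crossprod(fw$Xim[sel, , drop = FALSE], g)
    dconv_b[f] <- sum(g)
  }
  list(loss = loss,
       grads = list(conv_W = dconv_W, conv_b = dconv_b, W1 = dW1, b1 = db1,
                    W_out = dW_out, b_out = db_out))
}

#' @export
train_sequence_model.ltr_pooled_head <- function(model, train, validation,
                                                 cfg = train_config()) {
  X <- as.matrix(train$x)
  Xv <- as.matrix(validation$x)
  enc <- encode_labels(train$y, class_names = if (model$task == "family")
    model$class_names else NULL)
  enc_val <- encode_labels(validation$y, class_names = if (model$task == "family")
    model$class_names else NULL)
  wts <- sample_weights(enc, cfg)
  wts_val <- sample_weights(enc_val, cfg)
  cfg_m <- model$config
  batch_fn <- function(params, idx) {
    pooled_loss_grad(params, X[idx, , drop = FALSE], enc$y[idx], wts[idx],
                     enc$binary, cfg_m)
  }
  val_fn <- function(params) {
    fw <- pooled_forward(params, Xv, cfg_m)
    r <- pooled_metrics(fw$logits, enc_val, wts_val)
    list(loss = r$loss, f1 = r$f1)
  }
  fit <- fit_loop(model$params, length(enc$y), batch_fn, val_fn, cfg)
  model$params <- fit$params
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$fitted <- TRUE
  model
}

pooled_metrics <- function(logits, enc, w) {
  if (enc$binary) {
    z <- logits[, 1]
    loss <- sum(w * (pmax(z, 0) - z * enc$y + log1p(exp(-abs(z))))) / sum(w)
    pred <- enc$class_names[(z >= 0) + 1L]
    f1 <- compute_metrics(enc$class_names[enc$y + 1L], pred,
                          averaging = "binary",
                          positive = enc$class_names[2])$f1
  } else {
    zm <- logits - apply(logits, 1, max)
    p <- exp(zm) / rowSums(exp(zm))
    loss <- -sum(w * log(p[cbind(seq_along(enc$y), enc$y + 1L)])) / sum(w)
    pred <- enc$class_names[max.col(p, ties.method = "first")]
    f1 <- compute_metrics(enc$class_names[enc$y + 1L], pred,
                          averaging = "weighted")$f1
  }
  list(loss = loss, f1 = f1)
}

#' Predict from a fitted pooled-embedding head
#'
#' @param object An `ltr_pooled_head`.
#' @param X Embedding matrix (rows = sequences).
#' @param type `"class"`, `"prob"` or `"margin"`.
#' @param ... Unused.
#' @return Labels, probabilities, or logits.
#' @export
predict.ltr_pooled_head <- function(object, X,
                                    type = c("class", "prob", "margin"), ...) {
  type <- match.arg(type)
  logits <- pooled_forward(object$params, as.matrix(X), object$config)$logits
  K <- ncol(logits)
  if (type == "margin") return(if (K == 1L) as.numeric(logits) else logits)
  if (K == 1L) {
    p <- 1 / (1 + exp(-logits[, 1]))
    prob <- cbind(1 - p, p)
    colnames(prob) <- object$class_names
    if (type == "prob") return(prob)
    object$class_names[(p >= 0.5) + 1L]
  } else {
    e <- exp(logits - apply(logits, 1, max))
    prob <- e / rowSums(e)
    colnames(prob) <- object$class_names
    if (type == "prob") return(prob)
    object$class_names[max.col(prob, ties.method = "first")]
  }
}

#' @method tidy ltr_pooled_head
#' @export
tidy.ltr_pooled_head <- function(x, ...) {
  if (is.null(x$history)) rlang::abort("model is not trained")
  x$history
}

#' @method glance ltr_pooled_head
#' @export
glance.ltr_pooled_head <- function(x, ...) {
  tibble(kind = "pooled_head", task = x$task,
         input_dim = x$config$input_dim, n_filters = x$config$n_filters,
         dense_units = x$config$dense_units, fitted = x$fitted,
         best_epoch = if (is.null(x$best_epoch)) NA_integer_ else x$best_epoch)
}
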