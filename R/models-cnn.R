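# CNN-LSTM track: an input layer of one-hot encoded sequence, a 1-D
# convolutional layer, max pooling, an LSTM layer, and the task output node
# (sigmoid for binary tasks, 15-way softmax for the family task). Padded
# positions are dropped before encoding, so they are masked out of the
# convolutional and recurrent passes by construction.

#' Build an (untrained) CNN-LSTM sequence classifier
#'
#' @param n_filters Number of first-layer convolution filters.
#' @param filter_width Filter width in bases (sized to span typical TFBS
#'   motif widths so filter-to-motif mapping stays meaningful).
#' @param pool_size Max-pooling window.
#' @param lstm_units LSTM hidden units.
#' @param task `"ltr_detection"`, `"superfamily"` (binary heads) or
#'   `"family"` (softmax head over `class_names`).
#' @param class_names Class names; defaults to `FALSE`/`TRUE` for binary
#'   tasks and [ltr_family_names()] for the family task.
#' @param L_max Maximum encoded sequence length the model expects.
#' @param forget_bias Initial forget-gate bias. Remember-biased gates (the
#'   default 3) keep gradients alive across the hundreds of pooled steps a
#'   multi-kilobase sequence produces; without them the recurrent pass
#'   forgets — and attribution cannot see — the 5' half of the input.
#' @param bidirectional Run the LSTM in both directions and concatenate the
#'   final states (default). A single forward pass privileges the 3' end of
#'   the sequence: its readout sits there, so distant 5' features neither
#'   drive predictions nor receive attribution.
#' @param seed Seed for weight initialisation.
#' @return A handle of class `ltr_cnn_lstm` (`fitted = FALSE`).
#' @export
build_cnn_lstm <- function(n_filters = 64L, filter_width = 12L, pool_size = 4L,
                           lstm_units = 64L,
                           task = c("ltr_detection", "superfamily", "family"),
                           class_names = NULL, L_max = 4000L,
                           forget_bias = 3, bidirectional = TRUE, seed = 1L) {
  task <- match.arg(task)
  stopifnot(filter_width <= L_max)
  if (is.null(class_names)) {
    class_names <- switch(task,
                          ltr_detection = c("FALSE", "TRUE"),
                          superfamily = c("Ty1/Copia", "Ty3/Gypsy"),
                          family = ltr_family_names())
  }
  K <- if (task == "family") length(class_names) else 1L
  H <- as.integer(lstm_units)
  Ft <- as.integer(n_filters)
  wf <- as.integer(filter_width)
  params <- with_seed(seed, {
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- forget_bias
    out_in <- if (bidirectional) 2L * H else H
    p <- list(conv_W = glorot(4 * wf, Ft), conv_b = rep(0, Ft),
              Wx = glorot(Ft, 4 * H), Wh = glorot(H, 4 * H), b = b,
              W_out = glorot(out_in, K), b_out = rep(0, K))
    if (bidirectional) {
      p$Wx_b <- glorot(Ft, 4 * H)
      p$Wh_b <- glorot(H, 4 * H)
      p$b_b <- b
    }
    p
  })
  structure(list(kind = "cnn_lstm", task = task, params = params,
                 config = list(n_filters = Ft, filter_width = wf,
                               pool_size = as.integer(pool_size),
                               lstm_units = H, L_max = as.integer(L_max),
                               bidirectional = bidirectional),
                 class_names = class_names, seed = as.integer(seed),
                 fitted = FALSE, history = NULL),
            class = "ltr_cnn_lstm")
}

#' Default family label set
#'
#' The 15 LTR retrotransposon family names used as the default family-task
#' classes. This list is a configuration default, not a fixed claim: pass
#' your own `class_names` to use a different family inventory.
#'
#' @return Character vector of 15 family names.
#' @export
ltr_family_names <- function() {
  c("Ale", "Alesia", "Angela", "Athila", "Bianca", "CRM", "Galadriel",
    "Ikeros", "Ivana", "Reina", "Retand", "SIRE", "TAR", "Tekay", "Tork")
}

#' Count trainable parameters of a CNN-LSTM handle
#'
#' @param model An `ltr_cnn_lstm` handle.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

cnn_batch_y <- function(labels, model) {
  enc <- encode_labels(labels, class_names = if (model$task == "family")
    model$class_names else NULL)
  enc
}

#' Train a sequence model with early stopping
#'
#' Minibatch Adam training with early stopping on the validation loss: the
#' weights of the best validation epoch are restored, training halts after
#' `patience` epochs without improvement. The binary tasks optimise binary
#' cross entropy; the family task optimises categorical cross entropy with
#' per-class weights.
#'
#' @param model An `ltr_cnn_lstm` or `ltr_pooled_head` handle.
#' @param train,validation Lists with elements `x` (an `ltr_onehot` batch for
#'   the CNN-LSTM, an embedding matrix for the pooled head) and `y` (labels).
#' @param cfg A [train_config()].
#' @return The fitted handle; per-epoch losses in `$history`.
#' @export
train_sequence_model <- function(model, train, validation, cfg = train_config()) {
  UseMethod("train_sequence_model")
}

#' @export
train_sequence_model.ltr_cnn_lstm <- function(model, train, validation,
                                              cfg = train_config()) {
  stopifnot(inherits(train$x, "ltr_onehot"), inherits(validation$x, "ltr_onehot"))
  enc <- cnn_batch_y(train$y, model)
  enc_val <- cnn_batch_y(validation$y, model)
  task_code <- if (enc$binary) 0L else 1L
  if (!enc$binary && model$task != "family") {
    abort("multiclass labels supplied to a binary-task model")
  }
  wts <- sample_weights(enc, cfg)
  wts_val <- sample_weights(enc_val, cfg)
  pool <- model$config$pool_size

  # Batches of similar length keep the padded tail short; the batch order is
  # reshuffled every epoch inside fit_loop.
  len_order <- order(train$x$lengths, decreasing = TRUE)
  rank_of <- match(seq_along(len_order), len_order)

  batch_fn <- function(params, idx) {
    idx <- len_order[sort(rank_of[idx])]
    Lb <- max(train$x$lengths[idx], 1L)
    codes <- train$x$codes[idx, seq_len(Lb), drop = FALSE]
    res <- nn_batch_grad_cpp(codes, params, pool, enc$y[idx], wts[idx],
                             task_code, TRUE)
    list(loss = res$loss, grads = res$grads)
  }
  val_fn <- function(params) {
    r <- nn_eval(validation$x, params, pool, enc_val, wts_val, task_code)
    list(loss = r$loss, f1 = r$f1)
  }
  fit <- fit_loop(model$params, length(enc$y), batch_fn, val_fn, cfg)
  model$params <- fit$params
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$fitted <- TRUE
  model
}

# Chunked evaluation: mean loss and F1 on an encoded set.
nn_eval <- function(batch, params, pool, enc, wts, task_code, chunk = 256L) {
  n <- length(enc$y)
  ord <- order(batch$lengths, decreasing = TRUE)
  loss <- 0
  logits <- matrix(0, n, max(1L, ncol(params$W_out)))
  for (grp in split(ord, ceiling(seq_along(ord) / chunk))) {
    Lb <- max(batch$lengths[grp], 1L)
    codes <- batch$codes[grp, seq_len(Lb), drop = FALSE]
    r <- nn_batch_grad_cpp(codes, params, pool, enc$y[grp], wts[grp],
                           task_code, FALSE)
    loss <- loss + r$loss * sum(wts[grp])
    logits[grp, ] <- r$logits
  }
  loss <- loss / sum(wts)
  if (task_code == 0L) {
    pred <- enc$class_names[(logits[, 1] >= 0) + 1L]
    truth <- enc$class_names[enc$y + 1L]
    f1 <- compute_metrics(truth, pred, averaging = "binary",
                          positive = enc$class_names[2])$f1
  } else {
    pred <- enc$class_names[max.col(logits, ties.method = "first")]
    truth <- enc$class_names[enc$y + 1L]
    f1 <- compute_metrics(truth, pred, averaging = "weighted")$f1
  }
  list(loss = loss, f1 = f1, logits = logits)
}

sample_weights <- function(enc, cfg) {
  if (is.null(cfg$class_weights)) return(rep(1, length(enc$y)))
  w <- cfg$class_weights[enc$class_names[enc$y + 1L]]
  unname(w)
}

#' Predict from a fitted CNN-LSTM
#'
#' @param object A fitted `ltr_cnn_lstm`.
#' @param batch An `ltr_onehot` batch.
#' @param type `"class"`, `"prob"` or `"margin"` (logits).
#' @param ... Unused.
#' @return Labels, a probability matrix, or logits.
#' @export
predict.ltr_cnn_lstm <- function(object, batch,
                                 type = c("class", "prob", "margin"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(batch, "ltr_onehot"))
  pool <- object$config$pool_size
  n <- nrow(batch$codes)
  K <- ncol(object$params$W_out)
  logits <- matrix(0, n, K)
  ord <- order(batch$lengths, decreasing = TRUE)
  for (grp in split(ord, ceiling(seq_along(ord) / 256L))) {
    Lb <- max(batch$lengths[grp], 1L)
    logits[grp, ] <- nn_logits_cpp(batch$codes[grp, seq_len(Lb), drop = FALSE],
                                   object$params, pool)
  }
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

#' @method tidy ltr_cnn_lstm
#' @export
tidy.ltr_cnn_lstm <- function(x, ...) {
  if (is.null(x$history)) abort("model is not trained")
  x$history
}

#' @method glance ltr_cnn_lstm
#' @export
glance.ltr_cnn_lstm <- function(x, ...) {
  tibble(kind = "cnn_lstm", task = x$task,
         n_filters = x$config$n_filters, filter_width = x$config$filter_width,
         pool_size = x$config$pool_size, lstm_units = x$config$lstm_units,
         n_parameters = n_parameters(x), fitted = x$fitted,
         best_epoch = if (is.null(x$best_epoch)) NA_integer_ else x$best_epoch)
}
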