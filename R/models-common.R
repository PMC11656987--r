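# Shared training configuration, class weighting and the Adam/early-stopping
# fit loop used by both network tracks.

#' Training configuration for the network models
#'
#' Defaults mirror the training regime of the sequence classifiers: Adam,
#' 15 epochs, batches of 64, early stopping with 3-epoch patience on the
#' validation set.
#'
#' @param optimizer Only `"adam"` is implemented.
#' @param epochs Maximum number of epochs.
#' @param batch_size Minibatch size (>= 1).
#' @param patience Early-stopping patience in epochs (< epochs).
#' @param learning_rate Adam step size.
#' @param loss `"binary_ce"` or `"categorical_ce_weighted"`.
#' @param class_weights Optional named per-class weights for the weighted
#'   categorical loss (see [class_weights()]).
#' @param seed Integer seed controlling initialisation and batch order.
#' @return A list of class `ltr_train_config`.
#' @export
train_config <- function(optimizer = "adam", epochs = 15L, batch_size = 64L,
                         patience = 3L, learning_rate = 1e-3,
                         loss = c("binary_ce", "categorical_ce_weighted"),
                         class_weights = NULL, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(identical(optimizer, "adam"), batch_size >= 1)
  if (patience >= epochs) abort("`patience` must be smaller than `epochs`")
  structure(list(optimizer = optimizer, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, loss = loss,
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "ltr_train_config")
}

#' Inverse-frequency class weights
#'
#' `weight_c = N / (K * n_c)`: the weighted mean of the weights under the
#' label frequencies is 1, so the loss scale is unchanged while rare classes
#' are up-weighted.
#'
#' @param labels Label vector (factor levels define the classes).
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L) abort("need at least 2 classes")
  if (any(tab == 0L)) {
    abort(sprintf("class '%s' has no observations", names(tab)[tab == 0][1]))
  }
  n <- sum(tab)
  k <- length(tab)
  setNames(as.numeric(n / (k * tab)), names(tab))
}

# Adam with early stopping over a caller-supplied batch-gradient closure.
# batch_fn(params, idx) -> list(loss, grads); val_fn(params) -> list(loss, f1).
fit_loop <- function(params, n_train, batch_fn, val_fn, cfg) {
  lr <- cfg$learning_rate
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  m_state <- lapply(params, function(p) p * 0)
  v_state <- lapply(params, function(p) p * 0)
  step <- 0L
  best <- list(val = Inf, params = params, epoch = 0L)
  history <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      idx_all <- sample.int(n_train)
      batches <- split(idx_all, ceiling(seq_along(idx_all) / cfg$batch_size))
      train_loss <- 0
      for (bi in seq_along(batches)) {
        res <- batch_fn(params, batches[[bi]])
        if (!is.finite(res$loss)) {
          abort(sprintf("non-finite training loss at epoch %d", epoch))
        }
        train_loss <- train_loss + res$loss * length(batches[[bi]])
        step <- step + 1L
        corr1 <- 1 - b1^step
        corr2 <- 1 - b2^step
        for (nm in names(params)) {
          g <- res$grads[[nm]]
          m_state[[nm]] <- b1 * m_state[[nm]] + (1 - b1) * g
          v_state[[nm]] <- b2 * v_state[[nm]] + (1 - b2) * g^2
          params[[nm]] <- params[[nm]] -
            lr * (m_state[[nm]] / corr1) / (sqrt(v_state[[nm]] / corr2) + eps)
        }
      }
      val <- val_fn(params)
      history[[epoch]] <- tibble(epoch = epoch,
                                 train_loss = train_loss / n_train,
                                 val_loss = val$loss, val_f1 = val$f1)
      if (val$loss < best$val - 1e-9) {
        best <- list(val = val$loss, params = params, epoch = epoch)
      } else if (epoch - best$epoch >= cfg$patience) {
        break
      }
    }
  })
  list(params = best$params, best_epoch = best$epoch,
       history = dplyr::bind_rows(history))
}

# Glorot-uniform initial weights.
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# Encode labels for a task: binary -> 0/1 numeric; family -> 0..K-1 with
# class names attached.
encode_labels <- function(labels, class_names = NULL) {
  if (is.logical(labels)) {
    return(list(y = as.numeric(labels), class_names = c("FALSE", "TRUE"),
                binary = TRUE))
  }
  f <- if (is.null(class_names)) factor(labels) else factor(labels, levels = class_names)
  if (anyNA(f)) abort("labels outside the configured class names")
  if (nlevels(f) == 2L) {
    list(y = as.numeric(f) - 1, class_names = levels(f), binary = TRUE)
  } else {
    list(y = as.numeric(f) - 1, class_names = levels(f), binary = FALSE)
  }
}
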