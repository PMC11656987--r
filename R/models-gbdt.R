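# Gradient-boosted decision-tree track on TF-IDF weighted TFBS features,
# plus the stratified cross-validation grid search used for model selection.

#' Train a gradient-boosted classifier on TFBS features
#'
#' Fits a gradient-boosted decision-tree ensemble (xgboost backend) on a
#' feature table, typically the TF-IDF transform of PWM occurrence counts.
#' Deterministic under `seed` (single-threaded training); the fitted tree
#' structures remain accessible for tree-based attribution.
#'
#' @param features A feature tibble (`seq_id` + numeric columns).
#' @param labels Label vector aligned with the feature rows: logical or
#'   2-level for binary tasks, a factor with more levels for the family task.
#' @param hyperparams List of hyperparameters: `nrounds`, `max_depth`, `eta`,
#'   `subsample`, `colsample_bytree`, `min_child_weight`.
#' @param seed Integer seed.
#' @return A fitted handle of class `ltr_gbdt`.
#' @export
train_gbdt <- function(features, labels,
                       hyperparams = list(nrounds = 200L, max_depth = 4L,
                                          eta = 0.1),
                       seed = 1L) {
  x <- feature_matrix_values(features)
  enc <- encode_labels(labels)
  if (length(unique(enc$y)) < 2L) abort("labels contain a single class")
  hp <- utils::modifyList(list(nrounds = 200L, max_depth = 4L, eta = 0.1,
                               subsample = 1, colsample_bytree = 1,
                               min_child_weight = 1), hyperparams)
  nclass <- length(enc$class_names)
  params <- list(max_depth = hp$max_depth, eta = hp$eta,
                 subsample = hp$subsample, colsample_bytree = hp$colsample_bytree,
                 min_child_weight = hp$min_child_weight,
                 nthread = 1, seed = seed)
  if (enc$binary) {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- nclass
  }
  dm <- xgboost::xgb.DMatrix(x, label = enc$y, nthread = 1)
  booster <- with_seed(seed, xgboost::xgb.train(params = params, data = dm,
                                                nrounds = hp$nrounds))
  structure(list(booster = booster, feature_names = colnames(x),
                 class_names = enc$class_names, binary = enc$binary,
                 hyperparams = hp, seed = seed, fitted = TRUE),
            class = "ltr_gbdt")
}

#' Predict from a fitted gradient-boosted classifier
#'
#' @param object An `ltr_gbdt` handle.
#' @param features Feature tibble with the training columns.
#' @param type `"class"`, `"prob"` (class probabilities) or `"margin"`.
#' @param ... Unused.
#' @return Class labels, a probability matrix, or margins.
#' @export
predict.ltr_gbdt <- function(object, features,
                             type = c("class", "prob", "margin"), ...) {
  type <- match.arg(type)
  x <- feature_matrix_values(features)[, object$feature_names, drop = FALSE]
  dm <- xgboost::xgb.DMatrix(x, nthread = 1)
  if (object$binary) {
    p <- predict(object$booster, dm,
                 outputmargin = (type == "margin"))
    if (type == "margin") return(as.numeric(p))
    prob <- cbind(1 - p, p)
    colnames(prob) <- object$class_names
    if (type == "prob") return(prob)
    object$class_names[(p >= 0.5) + 1L]
  } else {
    p <- predict(object$booster, dm, outputmargin = (type == "margin"))
    if (is.null(dim(p))) p <- matrix(p, nrow = nrow(x), byrow = TRUE)
    colnames(p) <- object$class_names
    if (type != "class") return(p)
    object$class_names[max.col(p, ties.method = "first")]
  }
}

#' @method glance ltr_gbdt
#' @export
glance.ltr_gbdt <- function(x, ...) {
  tibble(kind = "gbdt", n_features = length(x$feature_names),
         n_classes = length(x$class_names), nrounds = x$hyperparams$nrounds,
         max_depth = x$hyperparams$max_depth, eta = x$hyperparams$eta,
         seed = x$seed)
}

#' @method tidy ltr_gbdt
#' @export
tidy.ltr_gbdt <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  as_tibble(imp) |>
    dplyr::rename_with(tolower)
}

#' Grid search with stratified cross-validation
#'
#' Exhaustive search over a list of hyperparameter configurations, each
#' scored by mean F1 over stratified k-fold cross-validation.
#'
#' @param features Feature tibble.
#' @param labels Aligned label vector.
#' @param model_grid List of hyperparameter lists for [train_gbdt()].
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @param averaging F1 averaging passed to [compute_metrics()].
#' @return A list: `best_hyperparams`, `best_score`, and `results` (one row
#'   per configuration x fold).
#' @export
grid_search_cv <- function(features, labels, model_grid, k_folds = 5L,
                           seed = 1L, averaging = NULL) {
  if (length(model_grid) == 0L) abort("empty grid")
  labels_chr <- as.character(labels)
  if (is.null(averaging)) {
    averaging <- if (length(unique(labels_chr)) == 2L) "binary" else "weighted"
  }
  fold <- stratified_kfold(labels_chr, k_folds, seed = seed)
  rows <- list()
  for (gi in seq_along(model_grid)) {
    for (fi in seq_len(k_folds)) {
      tr <- fold != fi
      fit <- train_gbdt(features[tr, ], labels[tr],
                        hyperparams = model_grid[[gi]],
                        seed = derive_seed(seed, gi))
      pred <- predict(fit, features[!tr, ])
      f1 <- compute_metrics(labels_chr[!tr], pred, averaging = averaging)$f1
      rows[[length(rows) + 1L]] <- tibble(config = gi, fold = fi, f1 = f1)
    }
  }
  results <- dplyr::bind_rows(rows)
  means <- results |>
    dplyr::group_by(.data$config) |>
    dplyr::summarise(mean_f1 = mean(.data$f1), .groups = "drop")
  best <- means$config[which.max(means$mean_f1)]
  list(best_hyperparams = model_grid[[best]],
       best_score = max(means$mean_f1),
       best_config = best,
       results = results)
}
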