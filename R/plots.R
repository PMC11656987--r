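# ggplot2 visualisations for the result types.

#' @method autoplot ltr_track
#' @export
autoplot.ltr_track <- function(object, ...) {
  df <- tibble(position = seq_along(object$values) - 1L,
               importance = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$importance)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(title = object$seq_id, x = "position (bp)",
                  y = "importance") +
    ggplot2::theme_minimal()
  anch <- purrr::compact(object$anchors)
  if (length(anch)) {
    adf <- tibble(anchor = names(anch), position = unlist(anch))
    p <- p + ggplot2::geom_vline(data = adf,
                                 ggplot2::aes(xintercept = .data$position,
                                              colour = .data$anchor),
                                 linetype = "dashed")
  }
  p
}

#' Plot an anchor-centered median importance profile
#'
#' @param centered Output of [center_tracks()].
#' @param anchor Anchor name used in the title.
#' @return A ggplot object.
#' @export
plot_centered_profile <- function(centered, anchor = "anchor") {
  ggplot2::ggplot(centered$profile,
                  ggplot2::aes(x = .data$offset, y = .data$median)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("offset from %s (bp)", anchor),
                  y = "median importance") +
    ggplot2::theme_minimal()
}

#' @method autoplot ltr_edge_summary
#' @export
autoplot.ltr_edge_summary <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      pair = paste0(.data$canonical_t5, "..", .data$canonical_t3))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pair, -.data$total),
                                   y = .data$total)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d%%", .data$percent)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = "canonical edge pair", y = "assigned count") +
    ggplot2::theme_minimal()
}

#' @method autoplot ltr_cnn_lstm
#' @export
autoplot.ltr_cnn_lstm <- function(object, ...) {
  if (is.null(object$history)) abort("model is not trained")
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}

#' Plot mean |attribution| of the top features
#'
#' @param attribs An `ltr_attr_features` (e.g. from [tree_shap()]).
#' @param top_n Features shown.
#' @return A ggplot object.
#' @export
plot_top_features <- function(attribs, top_n = 20L) {
  stopifnot(inherits(attribs, "ltr_attr_features"))
  v <- attribs$values
  if (is.list(v)) v <- Reduce(`+`, lapply(v, abs)) / length(v) else v <- abs(v)
  df <- tibble(feature = colnames(v), mean_abs = colMeans(v)) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs)) |>
    utils::head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature,
                                                      .data$mean_abs),
                                   y = .data$mean_abs)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean |attribution|") +
    ggplot2::theme_minimal()
}
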