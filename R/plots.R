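#' Plot methods
#'
#' `autoplot()` methods give the standard diagnostic views: the first two
#' principal components colored by class (the ordinal gradient), per-epoch
#' training curves, per-slice Shapley contributions, the two-column
#' length/orientation importance heatmap, and the confusion matrix.
#'
#' @param object A radshap object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name radshap-plots
NULL

#' @rdname radshap-plots
#' @method autoplot radshap_scores
#' @export
autoplot.radshap_scores <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(class = factor(bpe_class_names()[.data$label],
      levels = bpe_class_names()))
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_viridis_d(end = 0.9) +
    ggplot2::labs(
      x = "PC1", y = "PC2", colour = "class",
      title = "Slices in the principal-component plane"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname radshap-plots
#' @method autoplot radshap_classifier
#' @export
autoplot.radshap_classifier <- function(object, ...) {
  df <- object$history %>%
    tidyr::pivot_longer(-"epoch", names_to = "series", values_to = "value") %>%
    tidyr::separate("series", c("set", "metric"), sep = "_", extra = "merge")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
      colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "Training history",
      subtitle = sprintf("checkpoint at epoch %d", object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' @rdname radshap-plots
#' @param slice_id Slice whose contributions to draw.
#' @export
plot_shap_slice <- function(object, slice_id, ...) {
  stopifnot(inherits(object, "radshap_shap"))
  if (!slice_id %in% names(object$shap_values)) {
    rs_abort(paste0("slice not in explanation: ", slice_id),
      "radshap_shap_error")
  }
  m <- object$shap_values[[slice_id]]
  df <- tibble(
    class = factor(rep(bpe_class_names(), times = ncol(m)),
      levels = bpe_class_names()),
    component = factor(rep(paste0("PC", seq_len(ncol(m))), each = 4)),
    shapley = as.numeric(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$shapley,
    fill = .data$shapley > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::facet_wrap(~class, nrow = 1) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c23b22", `FALSE` = "#2a6f97")) +
    ggplot2::labs(
      title = paste0("Shapley contributions for slice ", slice_id),
      y = "Shapley value (probability scale)", x = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname radshap-plots
#' @param mask_below Drop feature types under the percentile cut (mirrors the
#'   white cells of the reference heatmaps).
#' @method autoplot radshap_importance
#' @export
autoplot.radshap_importance <- function(object, mask_below = TRUE, ...) {
  df <- as_tibble(object$types)
  if (mask_below) df <- filter(df, .data$above_percentile)
  df <- df %>%
    arrange(.data$mean_scaled_length) %>%
    mutate(feature_type = factor(.data$feature_type, levels = .data$feature_type)) %>%
    tidyr::pivot_longer(c("rescaled_length", "mean_orientation"),
      names_to = "panel", values_to = "value") %>%
    mutate(panel = factor(ifelse(.data$panel == "rescaled_length",
      "length [0,1]", "orientation"),
    levels = c("length [0,1]", "orientation")))
  ggplot2::ggplot(df, ggplot2::aes("", .data$feature_type, fill = .data$value)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~panel, nrow = 1) +
    ggplot2::scale_fill_gradient2(low = "#2a6f97", mid = "white",
      high = "#c23b22", midpoint = 0) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = NULL,
      title = "Shapley-scaled feature-type importance"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname radshap-plots
#' @method autoplot radshap_evaluation
#' @export
autoplot.radshap_evaluation <- function(object, ...) {
  cm <- object$confusion
  df <- as_tibble(as.data.frame(as.table(cm)))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(bpe_class_names())) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2a6f97") +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.3f)",
      object$accuracy)) +
    ggplot2::theme_minimal()
}
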