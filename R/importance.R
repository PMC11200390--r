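#' Shapley-scaled loading-vector arithmetic
#'
#' Every radiomic feature i owns a k-dimensional vector of loadings
#' `phi_i = (phi_i1, ..., phi_ik)` across the retained principal components.
#' Its plain Euclidean length is `V(X_i) = sqrt(sum_j phi_ij^2)`. Scaling
#' each coordinate by the Shapley value `alpha_j` of the corresponding
#' component for the explained prediction gives the Shapley-scaled length
#' `V_SHAP(X_i) = sqrt(sum_j (alpha_j phi_ij)^2)` — the feature's importance
#' for that prediction — and the signed orientation
#' `O(X_i) = sum_j alpha_j phi_ij`, whose sign says whether the feature pushes
#' the explained class probability up or down.
#'
#' @param loadings Numeric vector `phi_i` (one feature's loadings), or a
#'   features x components matrix for the vectorized forms.
#' @param alpha Numeric vector of Shapley values, one per component.
#' @return Nonnegative scalar lengths; signed orientation.
#' @examples
#' vector_length(c(3, 4, 0, 0)) # 5
#' shap_scaled_length(c(3, 4, 0, 0), c(2, 0, 0, 0)) # 6
#' shap_orientation(c(1, -1, 2, -2), c(1, 1, 1, 1)) # 0
#' @export
vector_length <- function(loadings) {
  if (is.matrix(loadings)) {
    return(sqrt(rowSums(loadings^2)))
  }
  sqrt(sum(loadings^2))
}

#' @rdname vector_length
#' @export
shap_scaled_length <- function(loadings, alpha) {
  if (is.matrix(loadings)) {
    stopifnot(ncol(loadings) == length(alpha))
    return(sqrt(rowSums(sweep(loadings, 2, alpha, "*")^2)))
  }
  if (length(loadings) != length(alpha)) {
    rs_abort("loadings and alpha must have equal length",
      "radshap_importance_error")
  }
  sqrt(sum((alpha * loadings)^2))
}

#' @rdname vector_length
#' @export
shap_orientation <- function(loadings, alpha) {
  if (is.matrix(loadings)) {
    stopifnot(ncol(loadings) == length(alpha))
    return(as.numeric(loadings %*% alpha))
  }
  if (length(loadings) != length(alpha)) {
    rs_abort("loadings and alpha must have equal length",
      "radshap_importance_error")
  }
  sum(alpha * loadings)
}

# Shared tail of the local and global reports: per-feature values ->
# type-level means -> [0,1] min-max rescale -> percentile mask.
build_importance <- function(pca, alpha, percentile, context) {
  phi <- pca$loadings
  features <- parse_feature_name(pca$feature_names) %>%
    mutate(
      unscaled_length = vector_length(phi),
      scaled_length = shap_scaled_length(phi, alpha),
      orientation = shap_orientation(phi, alpha)
    )
  types <- features %>%
    group_by(.data$feature_type) %>%
    summarise(
      n_features = n(),
      mean_scaled_length = mean(.data$scaled_length),
      mean_orientation = mean(.data$orientation),
      .groups = "drop"
    )
  rng <- range(types$mean_scaled_length)
  types$rescaled_length <- if (diff(rng) > 0) {
    (types$mean_scaled_length - rng[1]) / diff(rng)
  } else {
    rep(0, nrow(types)) # degenerate: all type means identical
  }
  thr <- as.numeric(quantile(types$mean_scaled_length, percentile / 100,
    type = 7))
  types$above_percentile <- types$mean_scaled_length >= thr
  types <- arrange(types, dplyr::desc(.data$mean_scaled_length))
  structure(
    list(
      features = features,
      types = types,
      percentile = percentile,
      threshold = thr,
      context = context
    ),
    class = "radshap_importance"
  )
}

#' Local explainability: feature importance for one prediction
#'
#' Takes the Shapley row of the slice's *predicted* class (predictions, not
#' ground-truth labels, are what is being explained), scales the loading
#' matrix with it, and reports per-feature Shapley-scaled lengths and
#' orientations (see [vector_length()]). Features are then pooled by feature
#' type (terminal name token, across filters and texture-matrix classes),
#' lengths and orientations averaged per type, type-level lengths min-max
#' rescaled to `[0, 1]`, and types below the percentile cut (default 75th, by
#' linear interpolation) masked out. Orientations are reported unrescaled.
#'
#' @param pca A `radshap_pca`.
#' @param explanation A `radshap_shap` from [explain_shap()].
#' @param slice_id Slice to explain (must be in the explanation).
#' @param percentile Percentile cut in `[0, 100]`.
#' @return A `radshap_importance` object; `$features` holds per-feature
#'   values, `$types` the aggregated report (`feature_type`,
#'   `mean_scaled_length`, `rescaled_length`, `mean_orientation`,
#'   `above_percentile`).
#' @export
local_importance <- function(pca, explanation, slice_id, percentile = 75) {
  stopifnot(inherits(pca, "radshap_pca"), inherits(explanation, "radshap_shap"))
  if (!slice_id %in% names(explanation$shap_values)) {
    rs_abort(paste0("slice not in explanation: ", slice_id),
      "radshap_importance_error")
  }
  if (nrow(pca$loadings) < 1 ||
    pca$n_components != explanation$n_components) {
    rs_abort("loading matrix and explanation have mismatched components",
      "radshap_importance_error")
  }
  pred <- explanation$predictions
  cls <- pred$.pred[match(slice_id, pred$slice_id)]
  alpha <- explanation$shap_values[[slice_id]][cls, ]
  build_importance(
    pca, alpha, percentile,
    context = list(scope = "local", slice_id = slice_id,
      predicted_class = cls)
  )
}

#' Global explainability: feature importance for one predicted class
#'
#' Pools every explained slice the model assigned to `predicted_class`.
#' The Shapley-scaled coefficients `alpha_j phi_ij` are averaged over those
#' slices *before* the Euclidean length is taken (because the loading matrix
#' is shared, this is the length under the subset-mean Shapley vector), then
#' type-level aggregation, `[0, 1]` rescaling and the percentile mask proceed
#' exactly as in [local_importance()].
#'
#' @inheritParams local_importance
#' @param predicted_class Integer 1..4.
#' @return A `radshap_importance` object.
#' @export
global_importance <- function(pca, explanation, predicted_class,
                              percentile = 75) {
  stopifnot(inherits(pca, "radshap_pca"), inherits(explanation, "radshap_shap"))
  predicted_class <- as.integer(predicted_class)
  stopifnot(predicted_class %in% 1:4)
  pred <- explanation$predictions
  ids <- pred$slice_id[pred$.pred == predicted_class]
  if (length(ids) == 0L) {
    rs_abort(
      paste0("no slices predicted as class ", predicted_class,
        " (", bpe_class_names()[predicted_class], ")"),
      "radshap_importance_error"
    )
  }
  alphas <- vapply(ids, function(id) {
    explanation$shap_values[[id]][predicted_class, ]
  }, numeric(explanation$n_components))
  alpha_bar <- rowMeans(matrix(alphas, nrow = explanation$n_components))
  build_importance(
    pca, alpha_bar, percentile,
    context = list(scope = "global", predicted_class = predicted_class,
      n_slices = length(ids))
  )
}

#' @rdname local_importance
#' @param x A `radshap_importance`.
#' @param path Output CSV path (type-level report).
#' @export
write_importance <- function(x, path) {
  stopifnot(inherits(x, "radshap_importance"))
  readr::write_csv(
    x$types[, c("feature_type", "mean_scaled_length", "rescaled_length",
      "mean_orientation", "above_percentile")],
    path, progress = FALSE
  )
  invisible(path)
}

#' @export
print.radshap_importance <- function(x, ...) {
  ctx <- x$context
  hdr <- if (ctx$scope == "local") {
    sprintf("slice %s, predicted class %d (%s)", ctx$slice_id,
      ctx$predicted_class, bpe_class_names()[ctx$predicted_class])
  } else {
    sprintf("class %d (%s), %d slices", ctx$predicted_class,
      bpe_class_names()[ctx$predicted_class], ctx$n_slices)
  }
  cat(sprintf("Shapley-scaled feature importance (%s, %s)\n", ctx$scope, hdr))
  cat(sprintf(
    "%d feature types, %d above the %g%% percentile cut\n",
    nrow(x$types), sum(x$types$above_percentile), x$percentile
  ))
  print(utils::head(as_tibble(x$types), 10))
  invisible(x)
}
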