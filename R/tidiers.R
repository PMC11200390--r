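#' Broom-style tidiers for fitted pipeline objects
#'
#' `tidy()` returns one observation per row (loadings, epochs, Shapley terms,
#' importance records, bootstrap metrics); `glance()` returns a one-row
#' summary.
#'
#' @param x A fitted radshap object.
#' @param ... Unused.
#' @return A tibble.
#' @name radshap-tidiers
NULL

#' @rdname radshap-tidiers
#' @method tidy radshap_pca
#' @export
tidy.radshap_pca <- function(x, ...) {
  phi <- x$loadings
  tibble(
    feature = rep(x$feature_names, times = ncol(phi)),
    component = rep(seq_len(ncol(phi)), each = nrow(phi)),
    loading = as.numeric(phi)
  )
}

#' @rdname radshap-tidiers
#' @method glance radshap_pca
#' @export
glance.radshap_pca <- function(x, ...) {
  tibble(
    n_features = length(x$feature_names),
    n_components = x$n_components,
    n_train = x$n_train,
    n_dropped = length(x$dropped_features),
    cumulative_evr = sum(x$explained_variance_ratio)
  )
}

#' @rdname radshap-tidiers
#' @method tidy radshap_classifier
#' @export
tidy.radshap_classifier <- function(x, ...) {
  x$history
}

#' @rdname radshap-tidiers
#' @method glance radshap_classifier
#' @export
glance.radshap_classifier <- function(x, ...) {
  tibble(
    n_inputs = x$n_inputs,
    n_blocks = length(x$config$architecture),
    n_epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    best_val_accuracy = x$history$val_accuracy[x$best_epoch]
  )
}

#' @rdname radshap-tidiers
#' @method tidy radshap_shap
#' @export
tidy.radshap_shap <- function(x, ...) {
  k <- x$n_components
  bind_rows(lapply(names(x$shap_values), function(id) {
    m <- x$shap_values[[id]]
    tibble(
      slice_id = id,
      class = rep(1:4, times = k),
      component = rep(seq_len(k), each = 4),
      shapley = as.numeric(m)
    )
  }))
}

#' @rdname radshap-tidiers
#' @method glance radshap_shap
#' @export
glance.radshap_shap <- function(x, ...) {
  tibble(
    n_slices = length(x$shap_values),
    n_components = x$n_components,
    base_minimal = x$base_values[1],
    base_mild = x$base_values[2],
    base_moderate = x$base_values[3],
    base_marked = x$base_values[4]
  )
}

#' @rdname radshap-tidiers
#' @method tidy radshap_importance
#' @export
tidy.radshap_importance <- function(x, ...) {
  as_tibble(x$types)
}

#' @rdname radshap-tidiers
#' @method glance radshap_importance
#' @export
glance.radshap_importance <- function(x, ...) {
  tibble(
    scope = x$context$scope,
    predicted_class = x$context$predicted_class,
    n_types = nrow(x$types),
    n_above_percentile = sum(x$types$above_percentile),
    percentile = x$percentile,
    threshold = x$threshold
  )
}

#' @rdname radshap-tidiers
#' @method tidy radshap_evaluation
#' @export
tidy.radshap_evaluation <- function(x, ...) {
  x$bootstrap
}

#' @rdname radshap-tidiers
#' @method glance radshap_evaluation
#' @export
glance.radshap_evaluation <- function(x, ...) {
  tibble(
    n_slices = x$n_slices,
    accuracy = x$accuracy,
    kappa = x$kappa,
    adjacent_fraction = x$adjacent_fraction,
    p_accuracy = x$p_accuracy,
    n_resamples = x$n_resamples
  )
}
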