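#' Standardization + principal component analysis on the training split
#'
#' Features are z-scored with training-set mean and population SD (n
#' denominator), then decomposed by PCA. The model keeps the unit-norm
#' principal axes as the loading matrix phi (n_features x n_components):
#' component scores are the plain weighted sums `PC_j = sum_i phi_ij x_i` of
#' the standardized features. Columns are sign-fixed so that each column's
#' largest-magnitude coefficient is positive, making repeated fits (and all
#' Shapley-scaled orientations downstream) reproducible. Zero-variance
#' training features cannot be standardized; they are dropped with a warning
#' and recorded so that [transform_pca()] can align columns.
#'
#' @param train A `radshap_table` holding the training slices only.
#' @param n_components Number of components to retain
#'   (<= min(n_slices - 1, n_features)).
#' @return A `radshap_pca` list: `feature_names`, `feature_means`,
#'   `feature_sds`, `loadings` (features x components),
#'   `explained_variance_ratio`, `n_components`, `dropped_features`.
#' @export
fit_pca <- function(train, n_components = 4L) {
  stopifnot(inherits(train, "radshap_table"))
  n_components <- as.integer(n_components)
  X <- feature_matrix(train)
  if (n_components < 1L ||
    n_components > min(nrow(X) - 1L, ncol(X))) {
    rs_abort(
      paste0("n_components must be in 1..min(n_slices - 1, n_features) = ",
        min(nrow(X) - 1L, ncol(X))),
      "radshap_pca_error"
    )
  }
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, mu)^2)) # population SD
  keep <- sds > 0
  if (!any(keep)) {
    rs_abort("all features are constant on the training split",
      "radshap_pca_error")
  }
  dropped <- colnames(X)[!keep]
  if (length(dropped) > 0) {
    rs_inform(
      "dropping ", length(dropped),
      " zero-variance training feature(s): ",
      paste(utils::head(dropped, 5L), collapse = ", ")
    )
  }
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sds[keep], "/")
  fit <- stats::prcomp(Z, center = FALSE, scale. = FALSE, rank. = n_components)
  phi <- fit$rotation[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-|coefficient| entry positive per column
  for (j in seq_len(ncol(phi))) {
    i <- which.max(abs(phi[, j]))
    if (phi[i, j] < 0) phi[, j] <- -phi[, j]
  }
  total_var <- sum(colMeans(Z^2)) # population variances of standardized Z
  evr <- (fit$sdev^2 * (nrow(Z) - 1) / nrow(Z)) / total_var
  structure(
    list(
      feature_names = colnames(X)[keep],
      feature_means = mu[keep],
      feature_sds = sds[keep],
      loadings = phi,
      explained_variance_ratio = evr[seq_len(n_components)],
      n_components = n_components,
      dropped_features = dropped,
      n_train = nrow(X)
    ),
    class = "radshap_pca"
  )
}

#' Project a feature table onto a fitted PCA model
#'
#' Standardizes with the training-set mean/SD stored in the model and applies
#' the loading matrix: `score_sj = sum_i phi_ij (x_si - mean_i) / sd_i`.
#'
#' @param model A `radshap_pca`.
#' @param table A `radshap_table` whose feature columns cover the model's.
#' @return A `radshap_scores` tibble: `slice_id`, `label`, then `PC1..PCk`.
#' @export
transform_pca <- function(model, table) {
  stopifnot(inherits(model, "radshap_pca"), inherits(table, "radshap_table"))
  feats <- feature_cols(table)
  missing <- setdiff(model$feature_names, feats)
  if (length(missing) > 0) {
    rs_abort(
      paste0("table lacks model feature(s): ",
        paste(utils::head(missing, 5L), collapse = ", ")),
      "radshap_pca_error"
    )
  }
  X <- as.matrix(table[model$feature_names])
  Z <- sweep(sweep(X, 2, model$feature_means), 2, model$feature_sds, "/")
  S <- Z %*% model$loadings
  colnames(S) <- paste0("PC", seq_len(model$n_components))
  out <- bind_cols(
    tibble(slice_id = table$slice_id, label = table$label),
    as_tibble(as.data.frame(S, optional = TRUE))
  )
  class(out) <- c("radshap_scores", class(out))
  out
}

#' @rdname transform_pca
#' @param scores A `radshap_scores`.
#' @return `score_matrix()` returns the numeric slice-by-component matrix.
#' @export
score_matrix <- function(scores) {
  m <- as.matrix(scores[grep("^PC[0-9]+$", names(scores), value = TRUE)])
  rownames(m) <- scores$slice_id
  m
}

#' @export
print.radshap_pca <- function(x, ...) {
  cat(sprintf(
    "PCA model: %d features -> %d components (fit on %d slices)\n",
    length(x$feature_names), x$n_components, x$n_train
  ))
  cat(sprintf(
    "Cumulative explained variance ratio: %.3f\n",
    sum(x$explained_variance_ratio)
  ))
  if (length(x$dropped_features) > 0) {
    cat(sprintf("Dropped zero-variance features: %d\n",
      length(x$dropped_features)))
  }
  invisible(x)
}
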