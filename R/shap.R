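# Shapley attribution of class probabilities to principal-component inputs.
#
# Value function: v(S) = mean over background rows of the model probability
# when components in S take the explained slice's values and the rest keep
# the background row's values. With k components and k <= 15 every coalition
# is enumerated and the kernel-regression estimate is exact; the sampled
# kernel path exists for wider inputs only.

coalition_matrix <- function(k) {
  stopifnot(k >= 1, k <= 25)
  m <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- NULL
  m
}

# v(S) for a set of coalitions: returns |coalitions| x n_classes matrix.
coalition_values <- function(predict_fn, background, x, Z) {
  nb <- nrow(background)
  out <- matrix(NA_real_, nrow(Z), 4L)
  # one batched prediction per coalition; rows = background copies
  for (r in seq_len(nrow(Z))) {
    on <- Z[r, ] == 1L
    Xs <- background
    if (any(on)) Xs[, on] <- matrix(x[on], nb, sum(on), byrow = TRUE)
    out[r, ] <- colMeans(predict_fn(Xs))
  }
  out
}

kernel_weights <- function(sizes, k) {
  (k - 1) / (choose(k, sizes) * sizes * (k - sizes))
}

# Kernel SHAP for one slice: constrained weighted least squares over the
# enumerated (or sampled) coalitions, solved with the efficiency constraint
# sum(phi) = f(x) - E[f] eliminated by substitution. Returns 4 x k matrix.
kernel_shap_slice <- function(predict_fn, background, x, n_samples = NULL) {
  k <- length(x)
  if (k == 1L) {
    # closed form: the only player takes the whole gap to the base value
    v0 <- colMeans(predict_fn(background))
    v1 <- as.numeric(predict_fn(matrix(x, nrow = 1)))
    return(matrix(v1 - v0, 4L, 1L))
  }
  full <- is.null(n_samples) || k <= 15
  if (full) {
    Z <- coalition_matrix(k)
    Z <- Z[rowSums(Z) > 0 & rowSums(Z) < k, , drop = FALSE]
  } else {
    sizes <- sample(1:(k - 1), n_samples, replace = TRUE,
      prob = kernel_weights(1:(k - 1), k) * choose(k, 1:(k - 1)))
    Z <- t(vapply(sizes, function(s) {
      z <- integer(k)
      z[sample.int(k, s)] <- 1L
      z
    }, integer(k)))
  }
  w <- kernel_weights(rowSums(Z), k)
  v0 <- colMeans(predict_fn(background))
  v1 <- as.numeric(predict_fn(matrix(x, nrow = 1)))
  V <- coalition_values(predict_fn, background, x, Z)

  # substitute phi_k = delta - sum_{j<k} phi_j
  A <- Z[, -k, drop = FALSE] - Z[, k]
  XtWX <- crossprod(A, A * w)
  phi <- matrix(NA_real_, 4L, k)
  for (cls in 1:4) {
    delta <- v1[cls] - v0[cls]
    y <- V[, cls] - v0[cls] - Z[, k] * delta
    rhs <- crossprod(A, w * y)
    head_phi <- solve(XtWX, rhs)
    phi[cls, ] <- c(head_phi, delta - sum(head_phi))
  }
  phi
}

#' Shapley attribution of class probabilities to principal components
#'
#' Explains each slice's four class probabilities in terms of its
#' principal-component inputs. Base values are the average model output per
#' class over the background set (by convention the full training-set
#' scores); per slice, a 4 x k Shapley array is produced whose class-k row
#' sums, together with that class's base value, to the model's probability
#' (efficiency). With `k <= 15` components all `2^k` coalitions are
#' enumerated and the kernel-regression estimate is exact.
#'
#' @param model A `radshap_classifier`.
#' @param background A `radshap_scores` used for the expectation in the value
#'   function (training-set scores in the standard workflow).
#' @param slices A `radshap_scores` with the slices to explain.
#' @param background_size Optional seeded subsample size for large background
#'   sets (a documented deviation from the full-training-set default).
#' @param seed Seed for the background subsample (and coalition sampling when
#'   `k > 15`).
#' @return A `radshap_shap` object: `base_values` (length 4),
#'   `shap_values` (list of 4 x k matrices keyed by slice), `predictions`
#'   (the model's [predict_classifier()] output for `slices`),
#'   `background_ref`.
#' @export
explain_shap <- function(model, background, slices, background_size = NULL,
                         seed = 1L) {
  stopifnot(inherits(model, "radshap_classifier"),
    inherits(background, "radshap_scores"),
    inherits(slices, "radshap_scores"))
  B <- score_matrix(background)
  X <- score_matrix(slices)
  if (nrow(B) == 0L) rs_abort("empty background set", "radshap_shap_error")
  if (ncol(B) != model$n_inputs || ncol(X) != model$n_inputs) {
    rs_abort("component count does not match the model", "radshap_shap_error")
  }
  bg_ref <- paste0("background n=", nrow(B))
  if (!is.null(background_size) && background_size < nrow(B)) {
    B <- with_seed(seed, B[sample.int(nrow(B), background_size), , drop = FALSE])
    bg_ref <- paste0(bg_ref, " subsampled to ", background_size,
      " (seed ", seed, ")")
  }
  predict_fn <- function(M) predict_prob_matrix(model, M)
  base_values <- colMeans(predict_fn(B))
  shap_values <- with_seed(seed, {
    lapply(seq_len(nrow(X)), function(i) {
      kernel_shap_slice(predict_fn, B, X[i, ])
    })
  })
  names(shap_values) <- slices$slice_id
  structure(
    list(
      base_values = base_values,
      shap_values = shap_values,
      predictions = predict_classifier(model, slices),
      background_ref = bg_ref,
      n_components = model$n_inputs
    ),
    class = "radshap_shap"
  )
}

#' Exact Shapley values by coalition enumeration
#'
#' Independent oracle: for each component j, sums the weighted marginal
#' contributions `|S|! (k - |S| - 1)! / k!  * (v(S + j) - v(S))` over every
#' coalition S not containing j, with the same background-expectation value
#' function as [explain_shap()]. Feasible for `k <= 15`.
#'
#' @param model A `radshap_classifier`.
#' @param background A `radshap_scores` (or bare matrix).
#' @param x A single slice: numeric length-k vector of component scores (or a
#'   one-row `radshap_scores`).
#' @return A 4 x k matrix of Shapley values (rows = classes).
#' @export
exact_shapley <- function(model, background, x) {
  B <- if (inherits(background, "radshap_scores")) {
    score_matrix(background)
  } else {
    as.matrix(background)
  }
  if (inherits(x, "radshap_scores")) x <- as.numeric(score_matrix(x)[1, ])
  k <- length(x)
  if (k > 15) {
    rs_abort("exact enumeration limited to 15 components",
      "radshap_shap_error")
  }
  predict_fn <- function(M) predict_prob_matrix(model, M)
  Z <- coalition_matrix(k)
  V <- coalition_values(predict_fn, B, x, Z)
  # index coalitions by their bit code for O(1) lookup
  code <- as.integer(Z %*% 2L^(seq_len(k) - 1L))
  V <- V[order(code), , drop = FALSE] # row i holds coalition code i-1
  sizes <- rowSums(coalition_matrix(k))[order(code)]
  phi <- matrix(0, 4L, k)
  fact <- factorial(0:k)
  for (j in seq_len(k)) {
    bit <- 2L^(j - 1L)
    codes <- 0:(2^k - 1)
    without <- codes[bitwAnd(codes, bit) == 0L]
    for (s in without) {
      sz <- sizes[s + 1L]
      w <- fact[sz + 1L] * fact[k - sz] / fact[k + 1L]
      phi[, j] <- phi[, j] + w * (V[s + bit + 1L, ] - V[s + 1L, ])
    }
  }
  phi
}

#' @export
print.radshap_shap <- function(x, ...) {
  cat(sprintf(
    "Shapley explanations: %d slices x 4 classes x %d components\n",
    length(x$shap_values), x$n_components
  ))
  cat(sprintf("Base values: %s\n",
    paste(sprintf("%.3f", x$base_values), collapse = ", ")))
  cat(sprintf("Background: %s\n", x$background_ref))
  invisible(x)
}
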