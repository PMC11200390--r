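#' Confusion matrix over the four ordinal classes
#'
#' Rows are true classes, columns predicted, both ordered minimal to marked.
#'
#' @param truth,predicted Integer vectors in 1..4, equal length.
#' @return 4x4 integer matrix with class-name dimnames.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    rs_abort("truth and predicted must have equal length", "radshap_eval_error")
  }
  if (!all(truth %in% 1:4) || !all(predicted %in% 1:4)) {
    rs_abort("labels must lie in 1..4", "radshap_eval_error")
  }
  m <- matrix(0L, 4L, 4L,
    dimnames = list(truth = bpe_class_names(), predicted = bpe_class_names()))
  tab <- table(factor(truth, 1:4), factor(predicted, 1:4))
  m[] <- as.integer(tab)
  m
}

#' Cohen's kappa from a confusion matrix
#'
#' Unweighted kappa: `(p_o - p_e) / (1 - p_e)` with the chance agreement
#' `p_e` from the row/column marginals. The degenerate single-cell table
#' (`p_e = 1`) is defined as 1 when observed agreement is also perfect.
#'
#' @param confusion Square count matrix (rows truth, columns predicted).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n <= 0) rs_abort("empty confusion matrix", "radshap_eval_error")
  p_o <- sum(diag(confusion)) / n
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - p_e) < 1e-15) {
    if (abs(1 - p_o) < 1e-15) {
      return(1)
    }
    rs_abort("degenerate table: chance agreement is 1 but observed is not",
      "radshap_eval_error")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Adjacent-class share of the misclassifications
#'
#' Fraction of misclassified slices whose predicted and true classes differ
#' by exactly one ordinal level; `NA` when there are no misclassifications.
#'
#' @inheritParams cohens_kappa
#' @return Numeric in `[0, 1]`, or `NA_real_` with zero errors.
#' @export
adjacent_fraction <- function(confusion) {
  confusion <- as.matrix(confusion)
  idx <- abs(row(confusion) - col(confusion))
  errors <- sum(confusion[idx != 0])
  if (errors == 0) {
    return(NA_real_)
  }
  sum(confusion[idx == 1]) / errors
}

#' Bootstrap accuracy and kappa over prediction pairs
#'
#' Resamples the paired (truth, predicted) rows with replacement, computes
#' accuracy and Cohen's kappa per resample, and reports means with 2.5/97.5
#' percentile confidence bounds. Deterministic given `seed`.
#'
#' @param truth,predicted Integer vectors in 1..4.
#' @param n_resamples Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return A tibble with one row per metric (`accuracy`, `kappa`): `mean`,
#'   `ci_lower`, `ci_upper`; attribute `"draws"` holds the per-resample
#'   values.
#' @export
bootstrap_metrics <- function(truth, predicted, n_resamples = 10000L,
                              seed = 1L) {
  if (n_resamples < 100L) {
    rs_abort("n_resamples must be at least 100", "radshap_eval_error")
  }
  n <- length(truth)
  stopifnot(length(predicted) == n, n >= 1)
  # encode each (truth, predicted) pair as 1..16 and resample pair codes
  code <- (as.integer(truth) - 1L) * 4L + as.integer(predicted)
  acc <- numeric(n_resamples)
  kap <- numeric(n_resamples)
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      counts <- tabulate(code[sample.int(n, n, replace = TRUE)], nbins = 16L)
      cm <- matrix(counts, 4L, 4L, byrow = TRUE)
      acc[r] <- sum(diag(cm)) / n
      p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
      kap[r] <- if (abs(1 - p_e) < 1e-15) 1 else (acc[r] - p_e) / (1 - p_e)
    }
  })
  out <- tibble(
    metric = c("accuracy", "kappa"),
    mean = c(mean(acc), mean(kap)),
    ci_lower = unname(c(quantile(acc, 0.025, type = 7),
      quantile(kap, 0.025, type = 7))),
    ci_upper = unname(c(quantile(acc, 0.975, type = 7),
      quantile(kap, 0.975, type = 7)))
  )
  attr(out, "draws") <- tibble(accuracy = acc, kappa = kap)
  out
}

#' One-sample, one-sided t-test against chance
#'
#' Tests whether the mean of `values` exceeds `null_value` (default 0.25,
#' four-class chance level).
#'
#' @param values Numeric sample (>= 2 values, nonzero variance).
#' @param null_value Null mean.
#' @return The p-value.
#' @export
t_test_vs_chance <- function(values, null_value = 0.25) {
  if (length(values) < 2L) {
    rs_abort("need at least 2 values for a t-test", "radshap_eval_error")
  }
  if (stats::sd(values) == 0) {
    rs_abort(
      "zero variance: all values identical; report the constant value instead of a t-test",
      "radshap_eval_error"
    )
  }
  stats::t.test(values, mu = null_value, alternative = "greater")$p.value
}

#' Full evaluation report for a prediction set
#'
#' @param predictions A `radshap_predictions` (or any tibble with `label` and
#'   `.pred` integer columns).
#' @param n_resamples Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return A `radshap_evaluation`: `confusion`, `accuracy`,
#'   `adjacent_fraction`, `kappa`, `bootstrap` (tibble), `p_accuracy`,
#'   `n_slices`, `n_resamples`.
#' @export
evaluate_predictions <- function(predictions, n_resamples = 10000L, seed = 1L) {
  stopifnot(all(c("label", ".pred") %in% names(predictions)))
  truth <- predictions$label
  pred <- predictions$.pred
  cm <- confusion_matrix(truth, pred)
  boot <- bootstrap_metrics(truth, pred, n_resamples = n_resamples, seed = seed)
  draws <- attr(boot, "draws")
  p_acc <- if (stats::sd(draws$accuracy) == 0) {
    NA_real_
  } else {
    t_test_vs_chance(draws$accuracy, 0.25)
  }
  structure(
    list(
      confusion = cm,
      accuracy = sum(diag(cm)) / sum(cm),
      adjacent_fraction = adjacent_fraction(cm),
      kappa = cohens_kappa(cm),
      bootstrap = boot,
      p_accuracy = p_acc,
      n_slices = length(truth),
      n_resamples = as.integer(n_resamples)
    ),
    class = "radshap_evaluation"
  )
}

#' @export
print.radshap_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation on %d slices (%d bootstrap resamples)\n",
    x$n_slices, x$n_resamples))
  b <- x$bootstrap
  cat(sprintf(
    "  accuracy %.3f (bootstrap %.3f, 95%% CI %.3f-%.3f)\n",
    x$accuracy, b$mean[1], b$ci_lower[1], b$ci_upper[1]
  ))
  cat(sprintf(
    "  kappa    %.3f (bootstrap %.3f, 95%% CI %.3f-%.3f)\n",
    x$kappa, b$mean[2], b$ci_lower[2], b$ci_upper[2]
  ))
  cat(sprintf(
    "  adjacent-class share of errors: %s\n",
    ifelse(is.na(x$adjacent_fraction), "undefined (no errors)",
      sprintf("%.3f", x$adjacent_fraction))
  ))
  if (!is.na(x$p_accuracy)) {
    cat(sprintf("  t-test accuracy > 0.25: p = %.3g\n", x$p_accuracy))
  }
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
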