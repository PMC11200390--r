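#' Inverse-frequency class weights
#'
#' Weight for class c is `n_total / (4 * n_c)`: the standard balanced
#' heuristic for a weighted categorical cross-entropy. All-equal class counts
#' give weight 1 for every class, and `sum_c w_c n_c = n_total` always.
#'
#' @param labels Integer labels in 1..4; all four classes must be present.
#' @return Numeric length-4 vector of positive weights.
#' @examples
#' compute_class_weights(rep(1:4, c(200, 100, 100, 100)))
#' @export
compute_class_weights <- function(labels) {
  counts <- tabulate(as.integer(labels), nbins = 4L)
  if (any(counts == 0)) {
    rs_abort(
      paste0("class(es) absent from labels: ",
        paste(which(counts == 0), collapse = ", ")),
      "radshap_classifier_error"
    )
  }
  length(labels) / (4 * counts)
}

#' Train the feed-forward classifier
#'
#' Fits the compact feed-forward network on principal-component scores:
#' sequential blocks of dense, batch-normalization, ReLU and dropout layers,
#' a 4-unit softmax head, class-weighted categorical cross-entropy
#' (inverse-frequency weights from the training labels), and the Adam
#' optimizer. Weights are Glorot-uniform initialized, biases zero. Training
#' runs for exactly `config$epochs` epochs with seeded batch shuffling; after
#' each epoch the class-weighted validation loss is computed in inference
#' mode, and the parameter state with the lowest validation loss is the one
#' returned.
#'
#' @param train_scores,val_scores `radshap_scores` for the training and
#'   validation slices (see [transform_pca()]).
#' @param config A `radshap_config`; `architecture`, `dropout_rate`,
#'   `learning_rate`, `batch_size` and `epochs` are used here.
#' @param seed Integer seed controlling initialization, batch shuffling and
#'   dropout; `NULL` draws from the session RNG (for repeatability
#'   experiments over independent initializations).
#' @return A `radshap_classifier`: the checkpointed network, `history`
#'   (per-epoch train/val loss and accuracy tibble), `best_epoch`,
#'   `class_weights`, `config`.
#' @export
train_classifier <- function(train_scores, val_scores,
                             config = pipeline_config(), seed = config$seed) {
  stopifnot(inherits(train_scores, "radshap_scores"),
    inherits(val_scores, "radshap_scores"))
  config <- validate_config(unclass(config))
  Xtr <- score_matrix(train_scores)
  ytr <- train_scores$label
  Xva <- score_matrix(val_scores)
  yva <- val_scores$label
  if (ncol(Xtr) != ncol(Xva)) {
    rs_abort("train and validation scores have different widths",
      "radshap_classifier_error")
  }
  cw <- compute_class_weights(ytr)

  with_seed(seed, {
    net <- mlp_init(ncol(Xtr), config$architecture, 4L)
    opt <- adam_init(net)
    n <- nrow(Xtr)
    best <- list(loss = Inf, net = NULL, epoch = NA_integer_)
    hist <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      batch_losses <- numeric(length(starts))
      correct <- 0L
      for (k in seq_along(starts)) {
        idx <- ord[starts[k]:min(starts[k] + config$batch_size - 1L, n)]
        fwd <- mlp_forward(net, Xtr[idx, , drop = FALSE], training = TRUE,
          dropout = config$dropout_rate)
        net <- fwd$net # running statistics updated
        batch_losses[k] <- weighted_ce(fwd$P, ytr[idx], cw)
        correct <- correct + sum(max.col(fwd$P, ties.method = "first") == ytr[idx])
        grads <- mlp_backward(net, fwd, ytr[idx], cw, config$dropout_rate)
        step <- adam_step(net, grads, opt, config$learning_rate)
        net <- step$net
        opt <- step$state
      }
      val_fwd <- mlp_forward(net, Xva, training = FALSE)
      val_loss <- weighted_ce(val_fwd$P, yva, cw)
      val_acc <- mean(max.col(val_fwd$P, ties.method = "first") == yva)
      hist[[epoch]] <- tibble(
        epoch = epoch,
        train_loss = mean(batch_losses),
        train_accuracy = correct / n,
        val_loss = val_loss,
        val_accuracy = val_acc
      )
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, net = net, epoch = epoch)
      }
    }
    structure(
      list(
        net = best$net,
        best_epoch = best$epoch,
        best_val_loss = best$loss,
        history = bind_rows(hist),
        class_weights = cw,
        n_inputs = ncol(Xtr),
        config = config
      ),
      class = "radshap_classifier"
    )
  })
}

#' Predict class probabilities for principal-component scores
#'
#' Inference mode: dropout off, batch-norm layers using their running
#' statistics. The predicted class is the probability argmax, ties broken
#' toward the lower (less enhancing) class.
#'
#' @param model A `radshap_classifier`.
#' @param scores A `radshap_scores`.
#' @return A `radshap_predictions` tibble: `slice_id`, `label`,
#'   `.prob_minimal` .. `.prob_marked`, `.pred` (integer 1..4).
#' @export
predict_classifier <- function(model, scores) {
  stopifnot(inherits(model, "radshap_classifier"),
    inherits(scores, "radshap_scores"))
  X <- score_matrix(scores)
  if (ncol(X) != model$n_inputs) {
    rs_abort("score width does not match the model's input size",
      "radshap_classifier_error")
  }
  P <- predict_prob_matrix(model, X)
  colnames(P) <- paste0(".prob_", bpe_class_names())
  out <- bind_cols(
    tibble(slice_id = scores$slice_id, label = scores$label),
    as_tibble(as.data.frame(P, optional = TRUE)),
    tibble(.pred = max.col(P, ties.method = "first"))
  )
  class(out) <- c("radshap_predictions", class(out))
  out
}

# Bare matrix-in/matrix-out probability function (used by the SHAP module).
predict_prob_matrix <- function(model, X) {
  mlp_forward(model$net, X, training = FALSE)$P
}

#' @export
print.radshap_classifier <- function(x, ...) {
  cat(sprintf(
    "Feed-forward classifier: %d -> %s -> 4 (softmax)\n",
    x$n_inputs, paste(x$config$architecture, collapse = " -> ")
  ))
  cat(sprintf(
    "Best epoch %d/%d, validation loss %.4f, validation accuracy %.3f\n",
    x$best_epoch, nrow(x$history), x$best_val_loss,
    x$history$val_accuracy[x$best_epoch]
  ))
  invisible(x)
}
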