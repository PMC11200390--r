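test_that("class weights follow the inverse-frequency formula", {
  expect_equal(compute_class_weights(rep(1:4, each = 25)), rep(1, 4))
  w <- compute_class_weights(rep(1:4, c(200, 100, 100, 100)))
  expect_equal(w, c(0.625, 1.25, 1.25, 1.25))
  # algebraic identity: sum_c w_c n_c = n_total
  lab <- sample(1:4, 500, replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
  if (all(1:4 %in% lab)) {
    w <- compute_class_weights(lab)
    expect_equal(sum(w * tabulate(lab, 4)), length(lab))
  }
  expect_error(compute_class_weights(rep(1:3, 10)),
    class = "radshap_classifier_error")
})

test_that("equal weights reduce the loss to unweighted cross-entropy", {
  set.seed(1)
  P <- matrix(runif(40), 10, 4)
  P <- P / rowSums(P)
  y <- sample(1:4, 10, replace = TRUE)
  w_eq <- rep(1, 4)
  plain <- mean(-log(P[cbind(1:10, y)]))
  expect_equal(radshap:::weighted_ce(P, y, w_eq), plain, tolerance = 1e-10)
  # weighting reweighs per-sample terms multiplicatively
  w <- c(2, 1, 0.5, 1)
  expect_equal(radshap:::weighted_ce(P, y, w),
    mean(w[y] * -log(P[cbind(1:10, y)])), tolerance = 1e-12)
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(42)
  n <- 12L
  X <- matrix(rnorm(n * 3), n, 3)
  y <- sample(1:4, n, replace = TRUE)
  cw <- c(1.2, 0.8, 1, 1.1)
  net <- radshap:::mlp_init(3L, c(5L, 4L), 4L)
  loss_at <- function(net) {
    fwd <- radshap:::mlp_forward(net, X, training = TRUE, dropout = 0)
    radshap:::weighted_ce(fwd$P, y, cw)
  }
  fwd <- radshap:::mlp_forward(net, X, training = TRUE, dropout = 0)
  grads <- radshap:::mlp_backward(net, fwd, y, cw, 0)
  eps <- 1e-6
  check_param <- function(path_get, path_set, g) {
    p <- path_get(net)
    idx <- sample(length(p), min(4, length(p)))
    for (i in idx) {
      up <- net
      pp <- p
      pp[i] <- pp[i] + eps
      up <- path_set(up, pp)
      dn <- net
      pm <- p
      pm[i] <- pm[i] - eps
      dn <- path_set(dn, pm)
      fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-5)
    }
  }
  for (b in 1:2) {
    for (nm in c("W", "b", "gamma", "beta")) {
      check_param(
        function(net) net$blocks[[b]][[nm]],
        function(net, v) {
          net$blocks[[b]][[nm]][] <- v
          net
        },
        grads$blocks[[b]][[nm]]
      )
    }
  }
  check_param(function(net) net$out$W,
    function(net, v) {
      net$out$W[] <- v
      net
    }, grads$out$W)
})

test_that("training is seeded-deterministic with a complete history", {
  run <- tiny_model()
  cfg <- run$model$config
  m2 <- train_classifier(run$scores, run$scores, cfg, seed = 7L)
  expect_equal(run$model$history, m2$history, tolerance = 1e-12)
  expect_equal(nrow(run$model$history), cfg$epochs)
  expect_equal(run$model$best_epoch,
    which.min(run$model$history$val_loss))
})

test_that("checkpoint restore reproduces the best validation loss", {
  run <- tiny_model()
  P <- radshap:::predict_prob_matrix(run$model, score_matrix(run$scores))
  loss <- radshap:::weighted_ce(P, run$scores$label,
    run$model$class_weights)
  expect_equal(loss, run$model$best_val_loss, tolerance = 1e-6)
})

test_that("loss decreases over early epochs on separable data", {
  run <- separable_run(202L)
  h <- run$model$history
  expect_lt(mean(h$train_loss[8:10]), mean(h$train_loss[1:3]))
  expect_gte(h$val_accuracy[run$model$best_epoch], 0.85)
})

test_that("predictions are valid probability rows with argmax class", {
  run <- tiny_model()
  pr <- predict_classifier(run$model, run$scores)
  P <- as.matrix(pr[grep("^.prob_", names(pr))])
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(pr$.pred, max.col(P, ties.method = "first"))
  # inference is deterministic
  pr2 <- predict_classifier(run$model, run$scores)
  expect_identical(as.data.frame(pr), as.data.frame(pr2))
  # dimension mismatch errors
  bad <- run$scores[, 1:4]
  class(bad) <- class(run$scores)
  expect_error(predict_classifier(run$model, bad),
    class = "radshap_classifier_error")
})

test_that("a small network memorizes a small sample without dropout", {
  run <- tiny_model()
  sub <- run$scores[1:40, ]
  class(sub) <- class(run$scores)
  cfg <- pipeline_config(
    architecture = c(64L, 32L), dropout_rate = 0,
    learning_rate = 3e-3, epochs = 150L, batch_size = 40L
  )
  m <- train_classifier(sub, sub, cfg, seed = 3L)
  expect_lt(m$history$train_loss[cfg$epochs], 0.05)
})

test_that("a model trained on no signal stays at permutation-level accuracy", {
  run <- null_run(303L)
  acc <- run$eval$accuracy
  truth <- run$preds$label
  pred <- run$preds$.pred
  # permutation null: distribution of accuracy when predictions carry no
  # information about the labels
  set.seed(9)
  perm <- replicate(2000, mean(sample(pred) == truth))
  lo <- quantile(perm, 0.005)
  hi <- quantile(perm, 0.995)
  expect_gte(acc, lo - 1e-12)
  expect_lte(acc, hi + 1e-12)
})
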