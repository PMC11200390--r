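test_that("vector arithmetic matches hand values", {
  expect_equal(vector_length(c(3, 4, 0, 0)), 5)
  expect_equal(vector_length(c(0, 0, 0, 0)), 0)
  expect_equal(shap_scaled_length(c(3, 4, 0, 0), c(1, 1, 1, 1)),
    vector_length(c(3, 4, 0, 0)))
  expect_equal(shap_scaled_length(c(3, 4, 0, 0), c(0, 0, 0, 0)), 0)
  expect_equal(shap_scaled_length(c(3, 4, 0, 0), c(2, 0, 0, 0)), 6)
  expect_equal(shap_orientation(c(1, -1, 2, -2), c(1, 1, 1, 1)), 0)
  expect_equal(shap_orientation(c(1, 0, 0, 0), c(-2, 0, 0, 0)), -2)
  a <- c(0.3, -1.2, 0.5, 2)
  expect_equal(shap_orientation(c(1, 2, 3, 4), -a),
    -shap_orientation(c(1, 2, 3, 4), a))
  expect_error(shap_scaled_length(c(1, 2), c(1, 2, 3)),
    class = "radshap_importance_error")
})

test_that("vector operations match per-element arithmetic on random rows", {
  set.seed(12)
  for (rep in 1:5) {
    k <- sample(2:6, 1)
    phi <- rnorm(k)
    alpha <- rnorm(k)
    len <- 0
    slen <- 0
    ori <- 0
    for (j in seq_len(k)) {
      len <- len + phi[j]^2
      slen <- slen + (alpha[j] * phi[j])^2
      ori <- ori + alpha[j] * phi[j]
    }
    expect_equal(vector_length(phi), sqrt(len), tolerance = 1e-12)
    expect_equal(shap_scaled_length(phi, alpha), sqrt(slen), tolerance = 1e-12)
    expect_equal(shap_orientation(phi, alpha), ori, tolerance = 1e-12)
  }
})

test_that("scaled length obeys the max-|alpha| bound", {
  set.seed(13)
  phi <- matrix(rnorm(200 * 4), 200, 4)
  alpha <- rnorm(4)
  lhs <- shap_scaled_length(phi, alpha)
  rhs <- max(abs(alpha)) * vector_length(phi)
  expect_true(all(lhs <= rhs + 1e-12))
})

test_that("single-component alpha ranks types by mean absolute loading", {
  run <- tiny_model()
  ex <- explain_shap(run$model, run$scores, run$scores[1:1, ], seed = 1L)
  # overwrite with a single-entry alpha on the predicted class row
  cls <- ex$predictions$.pred[1]
  m <- ex$shap_values[[1]]
  m[] <- 0
  m[cls, 1] <- 2.7
  ex$shap_values[[1]] <- m
  imp <- local_importance(run$pca, ex, names(ex$shap_values)[1])
  types <- parse_feature_name(run$pca$feature_names)$feature_type
  want <- sort(tapply(abs(run$pca$loadings[, 1]), types, mean),
    decreasing = TRUE)
  expect_identical(imp$types$feature_type, names(want))
})

test_that("percentile masking keeps the expected number of types", {
  # 8 distinct type lengths at the 75th percentile -> exactly 2 kept
  nm <- generate_feature_names(16)
  pca <- list(
    feature_names = nm$raw,
    loadings = matrix(rep(seq_len(16), 4), 16, 4),
    n_components = 4L
  )
  class(pca) <- "radshap_pca"
  imp <- radshap:::build_importance(pca, c(1, 0, 0, 0), 75,
    list(scope = "local", slice_id = "x", predicted_class = 1L))
  n_types <- nrow(imp$types)
  expect_lte(sum(imp$types$above_percentile) / n_types, 0.25 + 1 / n_types)
  distinct8 <- tibble::tibble(
    feature_type = letters[1:8],
    mean_scaled_length = c(1, 2, 3, 4, 5, 6, 7, 8)
  )
  thr <- quantile(distinct8$mean_scaled_length, 0.75, type = 7)
  expect_equal(sum(distinct8$mean_scaled_length >= thr), 2L)
})

test_that("the percentile mask is invariant under the [0,1] rescale", {
  set.seed(14)
  for (rep in 1:20) {
    v <- runif(sample(5:40, 1), 0, 10)
    thr_raw <- quantile(v, 0.75, type = 7)
    r <- (v - min(v)) / (max(v) - min(v))
    thr_res <- quantile(r, 0.75, type = 7)
    expect_identical(v >= thr_raw, r >= thr_res)
  }
})

test_that("rescaled type lengths span [0,1] exactly", {
  run <- separable_run(202L)
  ex <- run$explanation
  imp <- local_importance(run$pca, ex, names(ex$shap_values)[1])
  expect_equal(min(imp$types$rescaled_length), 0)
  expect_equal(max(imp$types$rescaled_length), 1)
})

test_that("local importance equals the independent brute-force script", {
  run <- separable_run(202L)
  ex <- run$explanation
  id <- names(ex$shap_values)[7]
  imp <- local_importance(run$pca, ex, id)
  cls <- ex$predictions$.pred[match(id, ex$predictions$slice_id)]
  oracle <- oracle_importance(run$pca$loadings, run$pca$feature_names,
    ex$shap_values[[id]][cls, ], 75)
  got <- imp$types[match(oracle$feature_type, imp$types$feature_type), ]
  expect_equal(got$mean_scaled_length, oracle$mean_scaled_length,
    tolerance = 1e-10)
  expect_equal(got$mean_orientation, oracle$mean_orientation,
    tolerance = 1e-10)
  expect_equal(got$rescaled_length, oracle$rescaled_length, tolerance = 1e-10)
  expect_identical(got$above_percentile, oracle$above_percentile)
})

test_that("global importance equals the brute-force script with averaged alphas", {
  run <- separable_run(202L)
  ex <- run$explanation
  cls <- 2L
  ids <- ex$predictions$slice_id[ex$predictions$.pred == cls]
  imp <- global_importance(run$pca, ex, cls)
  alphas <- sapply(ids, function(id) ex$shap_values[[id]][cls, ])
  oracle <- oracle_importance(run$pca$loadings, run$pca$feature_names,
    rowMeans(alphas), 75)
  got <- imp$types[match(oracle$feature_type, imp$types$feature_type), ]
  expect_equal(got$mean_scaled_length, oracle$mean_scaled_length,
    tolerance = 1e-10)
  expect_identical(got$above_percentile, oracle$above_percentile)
})

test_that("a one-slice global report equals that slice's local report", {
  run <- separable_run(202L)
  ex <- run$explanation
  # restrict the explanation to a single slice
  id <- ex$predictions$slice_id[1]
  cls <- ex$predictions$.pred[1]
  ex1 <- ex
  ex1$shap_values <- ex$shap_values[id]
  ex1$predictions <- ex$predictions[1, ]
  g <- global_importance(run$pca, ex1, cls)
  l <- local_importance(run$pca, ex1, id)
  expect_equal(g$types$mean_scaled_length, l$types$mean_scaled_length,
    tolerance = 1e-12)
  expect_equal(g$types$mean_orientation, l$types$mean_orientation,
    tolerance = 1e-12)
})

test_that("opposite alphas cancel in the global average", {
  run <- tiny_model()
  ex <- explain_shap(run$model, run$scores, run$scores[1:2, ], seed = 1L)
  cls <- 1L
  a <- matrix(rnorm(16), 4, 4)
  ex$shap_values[[1]] <- a
  ex$shap_values[[2]] <- -a
  ex$predictions$.pred <- c(cls, cls)
  g <- global_importance(run$pca, ex, cls)
  expect_true(all(abs(g$types$mean_scaled_length) < 1e-12))
})

test_that("degenerate requests error explicitly", {
  run <- tiny_model()
  ex <- explain_shap(run$model, run$scores, run$scores[1:2, ], seed = 1L)
  expect_error(local_importance(run$pca, ex, "no-such-slice"),
    class = "radshap_importance_error")
  absent <- setdiff(1:4, ex$predictions$.pred)[1]
  if (!is.na(absent)) {
    expect_error(global_importance(run$pca, ex, absent),
      class = "radshap_importance_error")
  }
})
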