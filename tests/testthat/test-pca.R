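test_that("loadings match an independent covariance eigendecomposition", {
  tab <- get_fixture("tiny") # 40 features
  pca <- fit_pca(tab, 4)
  # oracle: population-standardize by hand, eigendecompose the covariance
  X <- feature_matrix(tab)
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, mu)^2))
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  ev <- eigen(cov(Z), symmetric = TRUE)
  for (j in 1:4) {
    a <- pca$loadings[, j]
    b <- ev$vectors[, j]
    # sign-align before comparing
    if (sum(a * b) < 0) b <- -b
    expect_equal(unname(a), unname(b), tolerance = 1e-6)
  }
})

test_that("loading columns are orthonormal and variance ratios monotone", {
  pca <- separable_run(202L)$pca
  G <- crossprod(pca$loadings)
  expect_equal(unname(G), diag(4), tolerance = 1e-8)
  evr <- pca$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_true(all(evr >= 0 & evr <= 1))
  expect_lte(sum(evr), 1 + 1e-12)
})

test_that("repeated fits are identical under the sign convention", {
  tab <- get_fixture("tiny")
  p1 <- fit_pca(tab, 4)
  p2 <- fit_pca(tab, 4)
  expect_identical(p1$loadings, p2$loadings)
  # each column's largest-magnitude coefficient is positive
  for (j in 1:4) {
    col <- p1$loadings[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("exact low-rank data is fully captured by as many components", {
  # rank-2 linear map of 2 latent factors, no feature noise beyond the map
  set.seed(88)
  n <- 120L
  Zl <- matrix(rnorm(n * 2), n, 2)
  W <- matrix(rnorm(2 * 20), 2, 20)
  nm <- generate_feature_names(20)$raw
  X <- Zl %*% W
  colnames(X) <- nm
  tab <- as_feature_table(dplyr::bind_cols(
    tibble::tibble(patient_id = sprintf("p%d", seq_len(n)),
      slice_id = sprintf("s%d", seq_len(n)),
      label = rep(1:4, length.out = n)),
    tibble::as_tibble(as.data.frame(X))
  ))
  pca <- fit_pca(tab, 3)
  expect_gte(sum(pca$explained_variance_ratio[1:2]), 0.999)
})

test_that("transform is the standardized loading dot product", {
  run <- separable_run(202L)
  tab40 <- get_fixture("tiny")
  pca <- fit_pca(tab40, 4)
  sc <- transform_pca(pca, tab40)
  # oracle: direct arithmetic on the 40-feature fixture
  X <- feature_matrix(tab40)[, pca$feature_names]
  S <- score_matrix(sc)
  for (i in c(1L, 17L, 40L)) {
    z <- (X[i, ] - pca$feature_means) / pca$feature_sds
    for (j in 1:4) {
      expect_equal(S[i, j], sum(pca$loadings[, j] * z), tolerance = 1e-10)
    }
  }
  # training-set scores are centered with nonincreasing variance
  expect_true(all(abs(colMeans(S)) < 1e-8))
  expect_true(all(diff(apply(S, 2, var)) <= 1e-12))
})

test_that("the training mean maps to the zero score vector", {
  tab <- get_fixture("tiny")
  pca <- fit_pca(tab, 4)
  mean_row <- tab[1, ]
  mean_row[feature_cols(tab)] <- as.list(pca$feature_means)
  sc <- transform_pca(pca, as_feature_table(mean_row))
  expect_true(all(abs(score_matrix(sc)) < 1e-10))
})

test_that("zero-variance features are dropped and columns realigned", {
  tab <- get_fixture("tiny")
  tab2 <- tab
  const_col <- feature_cols(tab2)[3]
  tab2[[const_col]] <- 1.5
  withr::with_options(list(radshap.verbose = TRUE), {
    expect_message(pca <- fit_pca(as_feature_table(tab2), 3), "zero-variance")
  })
  expect_identical(pca$dropped_features, const_col)
  sc <- transform_pca(pca, as_feature_table(tab2))
  expect_equal(nrow(score_matrix(sc)), nrow(tab2))
})

test_that("invalid component counts and constant tables error", {
  tab <- get_fixture("tiny")
  expect_error(fit_pca(tab, 1000), class = "radshap_pca_error")
  expect_error(fit_pca(tab, 0), class = "radshap_pca_error")
  const <- tab
  for (f in feature_cols(const)) const[[f]] <- 2
  expect_error(suppressMessages(fit_pca(as_feature_table(const), 2)),
    class = "radshap_pca_error")
})

test_that("reconstruction error is nonincreasing in component count", {
  tab <- get_fixture("tiny")
  X <- feature_matrix(tab)
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, mu)^2))
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  errs <- sapply(1:6, function(k) {
    pca <- fit_pca(tab, k)
    S <- Z %*% pca$loadings
    sum((Z - S %*% t(pca$loadings))^2)
  })
  expect_true(all(diff(errs) <= 1e-8))
})
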