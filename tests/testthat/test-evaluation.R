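test_that("confusion matrices count pairs in fixed class order", {
  cm <- confusion_matrix(1:4, 1:4)
  expect_equal(unname(cm), diag(1L, 4L))
  cm2 <- confusion_matrix(c(1, 1), c(2, 2))
  expect_equal(cm2["minimal", "mild"], 2L)
  expect_equal(sum(cm2), 2L)
  set.seed(3)
  t <- sample(1:4, 60, replace = TRUE)
  p <- sample(1:4, 60, replace = TRUE)
  cm3 <- confusion_matrix(t, p)
  expect_equal(unname(rowSums(cm3)), unname(tabulate(t, 4L)))
  expect_equal(sum(cm3), 60L)
  expect_error(confusion_matrix(c(1, 5), c(1, 1)), class = "radshap_eval_error")
})

test_that("kappa matches the direct formula and the e1071 cross-check", {
  expect_equal(cohens_kappa(diag(10, 4)), 1)
  expect_equal(cohens_kappa(matrix(c(25, 25, 25, 25), 2)), 0)
  # p_o = 0.7, p_e = 0.5 -> kappa 0.4
  tab <- matrix(c(20, 10, 5, 15), 2) # byrow: [[20,5],[10,15]]
  expect_equal(cohens_kappa(tab), 0.4, tolerance = 1e-12)
  skip_if_not_installed("e1071")
  set.seed(4)
  t <- sample(1:4, 200, replace = TRUE)
  p <- ifelse(runif(200) < 0.6, t, sample(1:4, 200, replace = TRUE))
  cm <- confusion_matrix(t, p)
  expect_equal(cohens_kappa(cm),
    e1071::classAgreement(cm)$kappa, tolerance = 1e-10)
})

test_that("degenerate single-cell tables follow the documented contract", {
  one <- matrix(0, 4, 4)
  one[2, 2] <- 17
  expect_equal(cohens_kappa(one), 1)
  bad <- matrix(0, 4, 4)
  bad[2, 3] <- 17 # single off-diagonal cell: marginals disjoint, p_e = 0
  expect_equal(cohens_kappa(bad), 0)
})

test_that("adjacent fraction isolates one-step errors", {
  m <- matrix(0L, 4, 4)
  m[1, 2] <- 7
  expect_equal(adjacent_fraction(m), 1)
  m2 <- matrix(0L, 4, 4)
  m2[1, 4] <- 3
  expect_equal(adjacent_fraction(m2), 0)
  expect_true(is.na(adjacent_fraction(diag(5L, 4))))
  m3 <- matrix(0L, 4, 4)
  m3[1, 2] <- 3
  m3[4, 1] <- 1
  expect_equal(adjacent_fraction(m3), 0.75)
})

test_that("bootstrap is seeded, degenerate-safe and brackets the estimate", {
  t <- rep(1:4, each = 30)
  p <- ifelse(seq_along(t) %% 5 == 0, pmax(1, t - 1), t)
  b1 <- bootstrap_metrics(t, p, n_resamples = 500L, seed = 9L)
  b2 <- bootstrap_metrics(t, p, n_resamples = 500L, seed = 9L)
  expect_equal(b1, b2, tolerance = 1e-14)
  acc <- mean(t == p)
  expect_lte(b1$ci_lower[1], acc)
  expect_gte(b1$ci_upper[1], acc)
  # all-correct predictions: CIs collapse to [1,1]
  ball <- bootstrap_metrics(1:4, 1:4, n_resamples = 200L, seed = 1L)
  expect_equal(ball$ci_lower, c(1, 1))
  expect_equal(ball$ci_upper, c(1, 1))
  expect_error(bootstrap_metrics(t, p, n_resamples = 50L),
    class = "radshap_eval_error")
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  wins <- 0L
  for (s in 1:10) {
    mk <- function(n, seed) {
      set.seed(seed)
      t <- sample(1:4, n, replace = TRUE)
      p <- ifelse(runif(n) < 0.8, t, sample(1:4, n, replace = TRUE))
      list(t = t, p = p)
    }
    small <- mk(100, s)
    big <- mk(1000, s + 100)
    w_small <- with(bootstrap_metrics(small$t, small$p, 400L, seed = s),
      ci_upper[1] - ci_lower[1])
    w_big <- with(bootstrap_metrics(big$t, big$p, 400L, seed = s),
      ci_upper[1] - ci_lower[1])
    if (w_big < w_small) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("kappa point estimate is consistent with its bootstrap mean", {
  run <- separable_run(202L)
  b <- run$eval$bootstrap
  draws <- attr(b, "draws")
  se <- sd(draws$kappa)
  expect_lt(abs(run$eval$kappa - b$mean[2]), 3 * se)
  # accuracy from the confusion matrix equals direct fraction-correct
  expect_equal(run$eval$accuracy,
    mean(run$preds$label == run$preds$.pred), tolerance = 1e-12)
})

test_that("the t-test against chance matches the closed form", {
  set.seed(11)
  v <- 0.25 + rnorm(40, sd = 0.03)
  p_pkg <- t_test_vs_chance(v)
  tstat <- (mean(v) - 0.25) / (sd(v) / sqrt(length(v)))
  p_direct <- stats::pt(tstat, df = length(v) - 1, lower.tail = FALSE)
  expect_equal(p_pkg, p_direct, tolerance = 1e-10)
  expect_lt(t_test_vs_chance(c(0.8, 0.9, 0.85, 0.87, 0.82)), 0.001)
  expect_error(t_test_vs_chance(rep(0.5, 10)), class = "radshap_eval_error")
  expect_error(t_test_vs_chance(0.5), class = "radshap_eval_error")
})

test_that("null jitter around chance yields unremarkable p-values", {
  ps <- sapply(1:10, function(s) {
    set.seed(s)
    jitter <- rnorm(25, sd = 0.02)
    t_test_vs_chance(c(0.25 + jitter, 0.25 - jitter))
  })
  # symmetric samples centred exactly on the null: p should hover near 0.5
  expect_true(all(ps > 0.3 & ps < 0.7))
})

test_that("evaluation reports are internally consistent", {
  run <- separable_run(202L)
  ev <- run$eval
  expect_equal(sum(ev$confusion), ev$n_slices)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  g <- glance(ev)
  expect_equal(g$accuracy, ev$accuracy)
  expect_lt(ev$p_accuracy, 1e-6) # strong signal on the separable fixture
})
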