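# Shared test helpers: memoized fixtures and pipeline runs (several
# acceptance properties reuse the same multi-seed experiments), a reduced
# training configuration for fixture-sized problems, and independent
# brute-force oracles.

options(radshap.verbose = FALSE)

.rs_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .rs_cache)) {
    assign(key, force(expr), .rs_cache)
  }
  get(key, .rs_cache)
}

get_fixture <- function(name, seed = NULL) {
  key <- paste0("fixture_", name, "_", ifelse(is.null(seed), "default", seed))
  memo(key, make_fixture(name, seed = seed))
}

# Training configuration sized for the fixtures (the package defaults are the
# full operating point; fixture problems are far smaller).
small_config <- function(...) {
  pipeline_config(
    architecture = c(64L, 32L), dropout_rate = 0.2, learning_rate = 1e-3,
    epochs = 40L, batch_size = 50L, bootstrap_n = 1000L, ...
  )
}

# Model trained on the tiny fixture (train = val = all slices: the point is a
# working model for attribution tests, not generalisation).
tiny_model <- function() {
  memo("tiny_model", {
    tab <- get_fixture("tiny")
    pca <- fit_pca(tab, 4)
    sc <- transform_pca(pca, tab)
    cfg <- pipeline_config(
      architecture = c(32L, 16L), dropout_rate = 0.2,
      learning_rate = 1e-3, epochs = 25L, batch_size = 10L
    )
    model <- train_classifier(sc, sc, cfg, seed = 7L)
    list(table = tab, pca = pca, scores = sc, model = model)
  })
}

# One full pipeline run on the separable fixture for a given simulation seed;
# memoized because several properties (accuracy, adjacent errors, planted
# signal recovery, orientation signs) are read off the same runs.
separable_run <- function(seed) {
  memo(paste0("sep_run_", seed), {
    tab <- make_fixture("separable", seed = seed)
    sp <- stratified_split(tab, seed = seed)
    pca <- fit_pca(split_subset(tab, sp, "train"), 4)
    tr <- transform_pca(pca, split_subset(tab, sp, "train"))
    va <- transform_pca(pca, split_subset(tab, sp, "val"))
    te <- transform_pca(pca, split_subset(tab, sp, "test"))
    model <- train_classifier(tr, va, small_config(), seed = seed)
    preds <- predict_classifier(model, te)
    ev <- evaluate_predictions(preds, n_resamples = 1000L, seed = seed)
    expl <- explain_shap(model, tr, te, background_size = 150L, seed = seed)
    list(
      table = tab, split = sp, pca = pca, train_scores = tr,
      test_scores = te, model = model, preds = preds, eval = ev,
      explanation = expl
    )
  })
}

# Pipeline run on the null fixture (no class signal).
null_run <- function(seed) {
  memo(paste0("null_run_", seed), {
    tab <- make_fixture("null", seed = seed)
    sp <- stratified_split(tab, seed = seed, min_fraction = 0.02)
    pca <- fit_pca(split_subset(tab, sp, "train"), 4)
    tr <- transform_pca(pca, split_subset(tab, sp, "train"))
    va <- transform_pca(pca, split_subset(tab, sp, "val"))
    te <- transform_pca(pca, split_subset(tab, sp, "test"))
    cfg <- pipeline_config(
      architecture = c(32L, 16L), dropout_rate = 0.2,
      learning_rate = 1e-3, epochs = 20L, batch_size = 50L
    )
    model <- train_classifier(tr, va, cfg, seed = seed)
    preds <- predict_classifier(model, te)
    ev <- evaluate_predictions(preds, n_resamples = 1000L, seed = seed)
    list(preds = preds, eval = ev)
  })
}

# The planted signal-carrying feature types of the simulator defaults.
signal_types <- c(
  "RunEntropy", "ZoneEntropy", "DependenceEntropy",
  "GrayLevelNonUniformityNormalized"
)

# ---- independent brute-force oracles ---------------------------------------

# Straight-line re-implementation of the per-feature / per-type importance
# procedure, deliberately written with base-R loops and its own name
# handling: feature type = last underscore-separated token.
oracle_importance <- function(loadings, feature_names, alpha, percentile) {
  n <- nrow(loadings)
  len <- numeric(n)
  ori <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    o <- 0
    for (j in seq_along(alpha)) {
      s <- s + (alpha[j] * loadings[i, j])^2
      o <- o + alpha[j] * loadings[i, j]
    }
    len[i] <- sqrt(s)
    ori[i] <- o
  }
  type <- vapply(strsplit(feature_names, "_"), function(p) p[length(p)], "")
  mlen <- tapply(len, type, mean)
  mori <- tapply(ori, type, mean)
  rng <- range(mlen)
  resc <- if (diff(rng) > 0) (mlen - rng[1]) / diff(rng) else rep(0, length(mlen))
  thr <- quantile(mlen, percentile / 100, type = 7, names = FALSE)
  data.frame(
    feature_type = names(mlen),
    mean_scaled_length = as.numeric(mlen),
    mean_orientation = as.numeric(mori),
    rescaled_length = as.numeric(resc),
    above_percentile = as.numeric(mlen) >= thr,
    stringsAsFactors = FALSE
  )
}

# Closed-form Shapley values for a linear model p(x) = c + B x with an
# independent background: alpha_j = B[, j] * (x_j - mean(background_j)).
oracle_linear_shapley <- function(B, x, background) {
  sweep(B, 2, x - colMeans(background), "*")
}
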