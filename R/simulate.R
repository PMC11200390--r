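#' Simulation specification for synthetic feature tables
#'
#' Defines the generative model used throughout testing: each patient draws
#' one ordinal enhancement class from `class_probs` and a patient-level latent
#' offset; each of the patient's slices sits at a latent position
#' `z` in `d_latent` dimensions, with the class gradient along latent axis 1
#' (class means at 0, e, 2e, 3e for `effect_size` e, unit slice-level noise);
#' observed features are a fixed linear map of `z` plus independent feature
#' noise. Only columns whose feature *type* is in `signal_feature_types` load
#' on axis 1, so class signal is confined to a known, recoverable set of
#' feature types. All slices of a patient share its class label.
#'
#' @param n_patients Number of patients.
#' @param slices_per_patient Single count, or length-2 range sampled uniformly
#'   per patient.
#' @param n_features Number of radiomic-style feature columns.
#' @param d_latent Latent dimensionality.
#' @param class_probs Length-4 class probabilities (sum to 1); default mimics
#'   the imbalance typical of enhancement grades.
#' @param effect_size Separation of adjacent class means on latent axis 1, in
#'   units of the slice-level latent SD (1).
#' @param within_patient_sd SD of the per-patient latent offset (all axes).
#' @param noise_sd SD of independent feature-level noise.
#' @param signal_feature_types Feature types carrying the class signal.
#' @param seed Integer seed.
#' @return A `radshap_sim_spec` list.
#' @export
simulation_spec <- function(n_patients = 60L,
                            slices_per_patient = 40L,
                            n_features = 1192L,
                            d_latent = 4L,
                            class_probs = c(0.4, 0.25, 0.2, 0.15),
                            effect_size = 3,
                            within_patient_sd = 0.3,
                            noise_sd = 0.5,
                            signal_feature_types = default_signal_types(),
                            seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients),
    slices_per_patient = as.integer(slices_per_patient),
    n_features = as.integer(n_features),
    d_latent = as.integer(d_latent),
    class_probs = as.numeric(class_probs),
    effect_size = as.numeric(effect_size),
    within_patient_sd = as.numeric(within_patient_sd),
    noise_sd = as.numeric(noise_sd),
    signal_feature_types = as.character(signal_feature_types),
    seed = as.integer(seed)
  )
  validate_sim_spec(spec)
}

default_signal_types <- function() {
  c(
    "RunEntropy", "ZoneEntropy", "DependenceEntropy",
    "GrayLevelNonUniformityNormalized"
  )
}

validate_sim_spec <- function(spec) {
  check <- function(ok, what) {
    if (!ok) rs_abort(paste0("invalid simulation spec: ", what), "radshap_sim_error")
  }
  check(spec$n_patients >= 1, "n_patients must be positive")
  check(length(spec$slices_per_patient) %in% 1:2 &&
    all(spec$slices_per_patient >= 1), "slices_per_patient must be positive")
  check(spec$n_features >= 10, "n_features must be >= 10")
  check(spec$d_latent >= 1, "d_latent must be positive")
  check(length(spec$class_probs) == 4 && all(spec$class_probs > 0) &&
    abs(sum(spec$class_probs) - 1) < 1e-12, "class_probs must be 4 positive values summing to 1")
  check(spec$effect_size >= 0, "effect_size must be nonnegative")
  check(spec$within_patient_sd >= 0, "within_patient_sd must be nonnegative")
  check(spec$noise_sd > 0, "noise_sd must be positive")
  structure(spec, class = "radshap_sim_spec")
}

#' Simulate a synthetic radiomic feature table
#'
#' Draws a feature table under the latent ordinal-gradient model of
#' [simulation_spec()]. Deterministic given `spec$seed`. The loading matrix is
#' drawn once per seed: entries on latent axes 2..d are Normal(0,
#' 1/sqrt(d_latent)) for every column, while axis 1 carries a fixed +1 loading
#' on signal-type columns and 0 elsewhere (the planted, positively oriented
#' signal direction).
#'
#' @param spec A `radshap_sim_spec`.
#' @return A validated `radshap_table`; attribute `"latent"` holds the true
#'   slice latent positions, attribute `"loading"` the generative map.
#' @export
simulate_feature_table <- function(spec) {
  spec <- validate_sim_spec(unclass(spec))
  with_seed(spec$seed, {
    names_tbl <- generate_feature_names(spec$n_features)
    d <- spec$d_latent
    p <- spec$n_features

    W <- matrix(rnorm(p * d, sd = 1 / sqrt(d)), nrow = p, ncol = d)
    signal <- names_tbl$feature_type %in% spec$signal_feature_types
    W[, 1] <- ifelse(signal, 1, 0)

    n_sl <- if (length(spec$slices_per_patient) == 2L) {
      sample(spec$slices_per_patient[1]:spec$slices_per_patient[2],
        spec$n_patients, replace = TRUE)
    } else {
      rep(spec$slices_per_patient, spec$n_patients)
    }
    cls <- sample(1:4, spec$n_patients, replace = TRUE, prob = spec$class_probs)
    offsets <- matrix(rnorm(spec$n_patients * d, sd = spec$within_patient_sd),
      nrow = spec$n_patients)

    n_total <- sum(n_sl)
    pat_idx <- rep(seq_len(spec$n_patients), times = n_sl)
    Z <- matrix(rnorm(n_total * d), nrow = n_total, ncol = d)
    Z <- Z + offsets[pat_idx, , drop = FALSE]
    Z[, 1] <- Z[, 1] + (cls[pat_idx] - 1) * spec$effect_size

    X <- Z %*% t(W) + matrix(rnorm(n_total * p, sd = spec$noise_sd),
      nrow = n_total)
    colnames(X) <- names_tbl$raw

    tbl <- bind_cols(
      tibble(
        patient_id = sprintf("P%03d", pat_idx),
        slice_id = sprintf("P%03d-S%03d", pat_idx,
          unlist(lapply(n_sl, seq_len))),
        label = cls[pat_idx]
      ),
      as_tibble(as.data.frame(X, optional = TRUE))
    )
    out <- as_feature_table(tbl)
    attr(out, "latent") <- Z
    attr(out, "loading") <- W
    out
  })
}

#' Named test fixtures
#'
#' Small, fully deterministic feature tables used throughout the test suite:
#' * `"tiny"` — 8 patients x 5 slices, 40 features (fast smoke tests);
#' * `"separable"` — 50 patients x 30 slices, 1192 features, effect size 3,
#'   feature noise 0.5: an ordinal gradient a linear read-out recovers well;
#' * `"null"` — 80 patients x 8 slices, 120 features, effect size 0 and no
#'   patient-level offsets: the fully exchangeable no-signal reference
#'   (slice-level resampling assumes exchangeable prediction pairs, so the
#'   null reference carries no latent structure of any kind);
#' * `"imbalanced"` — 50 patients x 20 slices with class probabilities
#'   (0.55, 0.25, 0.12, 0.08).
#'
#' @param name Fixture name.
#' @param seed Seed override (default: each fixture's registered seed).
#' @return A `radshap_table`.
#' @export
make_fixture <- function(name, seed = NULL) {
  registry <- list(
    tiny = simulation_spec(
      n_patients = 8L, slices_per_patient = 5L, n_features = 40L,
      effect_size = 3, seed = 109L # registry seed: all four classes present
    ),
    separable = simulation_spec(
      n_patients = 50L, slices_per_patient = 30L, n_features = 1192L,
      effect_size = 3, noise_sd = 0.5, seed = 202L
    ),
    null = simulation_spec(
      n_patients = 80L, slices_per_patient = 8L, n_features = 120L,
      effect_size = 0, within_patient_sd = 0, seed = 303L
    ),
    imbalanced = simulation_spec(
      n_patients = 50L, slices_per_patient = 20L, n_features = 120L,
      class_probs = c(0.55, 0.25, 0.12, 0.08), effect_size = 3,
      seed = 412L # registry seed: every class held by >= 4 patients
    )
  )
  if (!name %in% names(registry)) {
    rs_abort(
      paste0("unknown fixture '", name, "'; available: ",
        paste(names(registry), collapse = ", ")),
      "radshap_sim_error"
    )
  }
  spec <- registry[[name]]
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  simulate_feature_table(spec)
}
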