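#' Pipeline configuration
#'
#' Bundles every tunable of the classification pipeline. Defaults are the
#' tuned operating point: four principal components feeding four dense blocks
#' of 512/256/128/64 units, dropout 0.45, Adam at learning rate 1e-4, batches
#' of 50 slices, 150 epochs, 10,000 bootstrap resamples, and a 75th-percentile
#' cut for importance reports. The `extraction_provenance` block records the
#' upstream image-extraction settings for traceability only; no image handling
#' happens in this package.
#'
#' @param n_components Number of principal components kept as classifier
#'   inputs.
#' @param architecture Integer vector of dense-block widths.
#' @param dropout_rate Dropout fraction in `[0, 1)` applied in every block.
#' @param learning_rate Adam learning rate.
#' @param batch_size Training mini-batch size (slices).
#' @param epochs Number of training epochs (fixed; the best-validation-loss
#'   checkpoint is returned).
#' @param bootstrap_n Bootstrap resamples for evaluation.
#' @param percentile_cut Percentile (0-100) below which type-level importance
#'   is masked.
#' @param seed Integer seed or `NULL` for unseeded runs.
#' @param extraction_provenance Named list describing upstream feature
#'   extraction; free-form, recorded verbatim in outputs.
#' @return A `radshap_config` list.
#' @export
pipeline_config <- function(n_components = 4L,
                            architecture = c(512L, 256L, 128L, 64L),
                            dropout_rate = 0.45,
                            learning_rate = 1e-4,
                            batch_size = 50L,
                            epochs = 150L,
                            bootstrap_n = 10000L,
                            percentile_cut = 75,
                            seed = NULL,
                            extraction_provenance = default_provenance()) {
  cfg <- list(
    n_components = as.integer(n_components),
    architecture = as.integer(architecture),
    dropout_rate = as.numeric(dropout_rate),
    learning_rate = as.numeric(learning_rate),
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    bootstrap_n = as.integer(bootstrap_n),
    percentile_cut = as.numeric(percentile_cut),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    extraction_provenance = extraction_provenance
  )
  validate_config(cfg)
}

default_provenance <- function() {
  list(
    bin_width = 20, voxel_array_shift = 300, resampled_spacing = c(1, 1),
    pad_distance = 10, interpolator = "Bspline", precrop = TRUE
  )
}

validate_config <- function(cfg) {
  check <- function(ok, what) {
    if (!ok) rs_abort(paste0("invalid config: ", what), "radshap_config_error")
  }
  check(length(cfg$n_components) == 1 && !is.na(cfg$n_components) &&
    cfg$n_components >= 1, "n_components must be a positive integer")
  check(length(cfg$architecture) >= 1 && all(cfg$architecture >= 1),
    "architecture must be positive block widths")
  check(length(cfg$dropout_rate) == 1 && cfg$dropout_rate >= 0 &&
    cfg$dropout_rate < 1, "dropout_rate must be in [0, 1)")
  check(cfg$learning_rate > 0, "learning_rate must be positive")
  check(cfg$batch_size >= 1, "batch_size must be a positive integer")
  check(cfg$epochs >= 1, "epochs must be a positive integer")
  check(cfg$bootstrap_n >= 1, "bootstrap_n must be a positive integer")
  check(cfg$percentile_cut >= 0 && cfg$percentile_cut <= 100,
    "percentile_cut must be in [0, 100]")
  structure(cfg, class = "radshap_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    rs_abort(paste0("config file not found: ", path), "radshap_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipeline_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown) > 0) {
    rs_abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
      "radshap_config_error")
  }
  cfg <- utils::modifyList(unclass(base), raw)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config A `radshap_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "radshap_config"))
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @export
print.radshap_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  n_components : %d\n", x$n_components))
  cat(sprintf("  architecture : %s\n", paste(x$architecture, collapse = "-")))
  cat(sprintf("  dropout_rate : %g   learning_rate: %g\n",
    x$dropout_rate, x$learning_rate))
  cat(sprintf("  batch_size   : %d   epochs: %d\n", x$batch_size, x$epochs))
  cat(sprintf("  bootstrap_n  : %d   percentile_cut: %g\n",
    x$bootstrap_n, x$percentile_cut))
  cat(sprintf("  seed         : %s\n", if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
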