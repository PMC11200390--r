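#' Radiomic feature-name convention
#'
#' Radiomic feature columns follow the dominant extractor convention
#' `<filter>_<class>_<type>`: an image-filter tag (e.g. `"original"`,
#' `"log-sigma-2-0-mm-3D"`, `"wavelet-LH"`, `"lbp-2D"`), a feature class drawn
#' from the closed set `firstorder`, `shape2D`, `glcm`, `glszm`, `glrlm`,
#' `ngtdm`, `gldm`, and a terminal feature-type token (e.g. `"Entropy"`,
#' `"GrayLevelNonUniformity"`). Underscores separate the three parts; hyphens
#' are allowed inside a part. The feature *type* — the terminal token pooled
#' over filters and texture-matrix classes — is the unit at which importance
#' is aggregated and reported.
#'
#' @param raw Character vector of raw column names.
#' @return `parse_feature_name()` returns a tibble with one row per input and
#'   columns `raw`, `filter_tag`, `feature_class`, `feature_type`.
#' @examples
#' parse_feature_name("log-sigma-2-0-mm-3D_glrlm_GrayLevelNonUniformity")
#' parse_feature_name("original_firstorder_Entropy")
#' @export
parse_feature_name <- function(raw) {
  stopifnot(is.character(raw), length(raw) >= 1L)
  if (any(!nzchar(raw))) {
    rs_abort("feature names must be non-empty strings", "radshap_parse_error")
  }
  parts <- strsplit(raw, "_", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 3L, logical(1))
  if (any(bad)) {
    rs_abort(
      paste0(
        "cannot parse feature name(s): ",
        paste(utils::head(raw[bad], 5L), collapse = ", "),
        " (expected <filter>_<class>_<type>)"
      ),
      "radshap_parse_error"
    )
  }
  n_parts <- lengths(parts)
  feature_class <- vapply(
    seq_along(parts),
    function(i) parts[[i]][n_parts[i] - 1L],
    character(1)
  )
  unknown <- !(feature_class %in% feature_classes())
  if (any(unknown)) {
    rs_abort(
      paste0(
        "unrecognized feature class in column(s): ",
        paste(utils::head(raw[unknown], 5L), collapse = ", "),
        " (class token must be one of ",
        paste(feature_classes(), collapse = ", "), ")"
      ),
      "radshap_parse_error"
    )
  }
  tibble(
    raw = raw,
    filter_tag = vapply(
      seq_along(parts),
      function(i) paste(parts[[i]][seq_len(n_parts[i] - 2L)], collapse = "_"),
      character(1)
    ),
    feature_class = feature_class,
    feature_type = vapply(
      seq_along(parts),
      function(i) parts[[i]][n_parts[i]],
      character(1)
    )
  )
}

#' @rdname parse_feature_name
#' @param filter_tag,feature_class,feature_type Character vectors (recycled)
#'   with the three name parts.
#' @return `compose_feature_name()` returns the raw character names.
#' @export
compose_feature_name <- function(filter_tag, feature_class, feature_type) {
  if (any(!feature_class %in% feature_classes())) {
    rs_abort("unknown feature_class token", "radshap_parse_error")
  }
  paste(filter_tag, feature_class, feature_type, sep = "_")
}

#' @rdname parse_feature_name
#' @return `feature_classes()` returns the closed set of class tokens.
#' @export
feature_classes <- function() {
  c("firstorder", "shape2D", "glcm", "glszm", "glrlm", "ngtdm", "gldm")
}

# Canonical type token lists per feature class (extractor-style vocabulary).
feature_type_registry <- function() {
  list(
    firstorder = c(
      "Mean", "Median", "Entropy", "Uniformity", "Energy", "TotalEnergy",
      "Minimum", "Maximum", "Range", "Variance", "Skewness", "Kurtosis",
      "RootMeanSquared", "InterquartileRange", "MeanAbsoluteDeviation",
      "RobustMeanAbsoluteDeviation", "10Percentile", "90Percentile"
    ),
    shape2D = c(
      "MeshSurface", "PixelSurface", "Perimeter", "PerimeterSurfaceRatio",
      "Sphericity", "MajorAxisLength", "MinorAxisLength", "Elongation",
      "MaximumDiameter"
    ),
    glcm = c(
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
      "JointEntropy", "MaximumProbability", "SumAverage", "SumEntropy",
      "SumSquares", "MCC"
    ),
    glrlm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis"
    ),
    glszm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "ZoneEntropy", "ZonePercentage", "ZoneVariance"
    ),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"),
    gldm = c(
      "DependenceEntropy", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "DependenceVariance",
      "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
      "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
      "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis"
    )
  )
}

base_filter_tags <- function() {
  c(
    "original",
    "log-sigma-1-0-mm-3D", "log-sigma-2-0-mm-3D", "log-sigma-3-0-mm-3D",
    "wavelet-LL", "wavelet-LH", "wavelet-HL", "wavelet-HH",
    "lbp-2D", "square", "squareroot", "logarithm", "exponential", "gradient"
  )
}

#' Generate a deterministic list of radiomic-style feature names
#'
#' Builds `n_features` unique names crossing filter tags with feature classes
#' and type tokens. Names are grouped by feature type so that each included
#' type carries at least two distinct filter/class combinations once the list
#' is moderately long — type-level aggregation downstream is then always
#' exercised. Unlike a real extractor, shape descriptors are crossed with
#' filter tags like every other family; the generator trades that bit of
#' realism for uniform type coverage.
#'
#' @param n_features Number of names to generate (>= 10).
#' @return Tibble as from [parse_feature_name()], `n_features` rows, unique
#'   `raw` names; deterministic in `n_features`.
#' @examples
#' generate_feature_names(40)
#' @export
generate_feature_names <- function(n_features) {
  stopifnot(length(n_features) == 1L, n_features >= 10)
  n_features <- as.integer(n_features)
  registry <- feature_type_registry()
  pairs <- dplyr::bind_rows(imap(registry, function(types, class) {
    tibble(feature_class = class, feature_type = types)
  }))
  types <- sort(unique(pairs$feature_type))

  # Extend the filter list deterministically if more names are required than
  # the base grid provides.
  filters <- base_filter_tags()
  grid_size <- function(filters) nrow(pairs) * length(filters)
  k <- 4L
  while (grid_size(filters) < n_features) {
    filters <- c(filters, sprintf("log-sigma-%d-0-mm-3D", k))
    k <- k + 1L
  }

  blocks <- map(types, function(tp) {
    cls <- pairs$feature_class[pairs$feature_type == tp]
    tibble(
      filter_tag = rep(filters, times = length(cls)),
      feature_class = rep(cls, each = length(filters)),
      feature_type = tp
    )
  })

  # Round 1: first two combos of every type (guarantees >= 2 combos per
  # included type for lists covering all types); then remaining combos in
  # type-block order.
  first_two <- dplyr::bind_rows(map(blocks, ~ .x[1:2, ]))
  rest <- dplyr::bind_rows(map(blocks, ~ .x[-(1:2), ]))
  full <- dplyr::bind_rows(first_two, rest)
  out <- full[seq_len(n_features), ]

  # If the cut leaves the tail type with a single combo (possible only when
  # n_features splits the first-two region), drop that lone entry and extend
  # the preceding type with an unused combo instead, so every included type
  # keeps >= 2 combos.
  tail_type <- out$feature_type[n_features]
  if (sum(out$feature_type == tail_type) < 2L && n_features >= 4L) {
    prev_type <- out$feature_type[n_features - 1L]
    blk <- blocks[[match(prev_type, types)]]
    used <- paste(out$filter_tag, out$feature_class)[out$feature_type == prev_type]
    extra <- blk[!paste(blk$filter_tag, blk$feature_class) %in% used, ][1, ]
    out[n_features, ] <- extra
  }

  out %>%
    mutate(raw = compose_feature_name(filter_tag, feature_class, feature_type)) %>%
    select("raw", "filter_tag", "feature_class", "feature_type")
}
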