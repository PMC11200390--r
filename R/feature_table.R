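#' Slice-wise radiomic feature tables
#'
#' A feature table is a tibble with one row per MRI slice: metadata columns
#' `patient_id` (character), `slice_id` (character, unique), `label` (integer
#' 1..4 coding the ordinal enhancement classes minimal, mild, moderate,
#' marked), followed by one numeric column per radiomic feature named under
#' the `<filter>_<class>_<type>` convention of [parse_feature_name()].
#'
#' `as_feature_table()` validates an existing data frame and returns it as a
#' `radshap_table` tibble; `feature_cols()` lists its feature column names;
#' `feature_matrix()` extracts the numeric slice-by-feature matrix with
#' `slice_id` row names.
#'
#' @param x A data frame with the columns described above.
#' @param na_action `"error"` (default) rejects any non-finite feature value;
#'   `"impute_median"` replaces them by the column median (intended for use on
#'   a training split only — medians are computed from the rows given here).
#' @return A validated `radshap_table` tibble.
#' @export
as_feature_table <- function(x, na_action = c("error", "impute_median")) {
  na_action <- match.arg(na_action)
  x <- as_tibble(x)
  meta <- c("patient_id", "slice_id", "label")
  missing_meta <- setdiff(meta, names(x))
  if (length(missing_meta) > 0) {
    rs_abort(
      paste0("missing metadata column(s): ", paste(missing_meta, collapse = ", ")),
      "radshap_table_error"
    )
  }
  feats <- setdiff(names(x), meta)
  if (length(feats) < 1L) {
    rs_abort("feature table must contain at least one feature column",
      "radshap_table_error")
  }
  x$patient_id <- as.character(x$patient_id)
  x$slice_id <- as.character(x$slice_id)
  if (anyDuplicated(x$slice_id)) {
    rs_abort("duplicate slice_id values", "radshap_table_error")
  }
  lab <- x$label
  if (any(is.na(lab)) || !all(lab %in% 1:4)) {
    rs_abort("labels must all lie in 1..4 (minimal, mild, moderate, marked)",
      "radshap_table_error")
  }
  x$label <- as.integer(lab)
  # validates the naming convention; errors name the offending column
  invisible(parse_feature_name(feats))
  vals <- as.matrix(x[feats])
  if (!is.numeric(vals)) {
    rs_abort("feature columns must be numeric", "radshap_table_error")
  }
  bad <- !is.finite(vals)
  if (any(bad)) {
    if (na_action == "error") {
      cols <- feats[unique(col(vals)[bad])]
      rs_abort(
        paste0(
          "non-finite feature values in column(s): ",
          paste(utils::head(cols, 5L), collapse = ", "),
          "; use na_action = \"impute_median\" to impute (training split only)"
        ),
        "radshap_table_error"
      )
    }
    for (j in unique(col(vals)[bad])) {
      v <- vals[, j]
      v[!is.finite(v)] <- stats::median(v[is.finite(v)])
      vals[, j] <- v
    }
    x[feats] <- as_tibble(as.data.frame(vals))
    rs_inform("imputed non-finite feature values with column medians")
  }
  x <- x[c(meta, feats)]
  class(x) <- c("radshap_table", class(x))
  x
}

#' @rdname as_feature_table
#' @export
feature_cols <- function(x) {
  setdiff(names(x), c("patient_id", "slice_id", "label"))
}

#' @rdname as_feature_table
#' @export
feature_matrix <- function(x) {
  m <- as.matrix(x[feature_cols(x)])
  rownames(m) <- x$slice_id
  m
}

#' @rdname as_feature_table
#' @export
bpe_class_names <- function() {
  c("minimal", "mild", "moderate", "marked")
}

table_format <- function(path, format = c("auto", "csv", "parquet")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.parquet$", path, ignore.case = TRUE)) "parquet" else "csv"
  }
  if (format == "parquet" && !requireNamespace("arrow", quietly = TRUE)) {
    rs_abort("the 'arrow' package is required for Parquet I/O",
      "radshap_io_error")
  }
  format
}

#' Read and write feature tables
#'
#' CSV (via readr, >= 15 significant digits) and Parquet (via arrow, lossless
#' 64-bit) round-trips preserve row order, column order, labels and values.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"auto"`, `"csv"` or `"parquet"`.
#' @inheritParams as_feature_table
#' @return `read_feature_table()` returns a validated `radshap_table`.
#' @export
read_feature_table <- function(path, format = c("auto", "csv", "parquet"),
                               na_action = c("error", "impute_median")) {
  if (!file.exists(path)) {
    rs_abort(paste0("file not found: ", path), "radshap_io_error")
  }
  format <- table_format(path, match.arg(format))
  raw <- if (format == "parquet") {
    as_tibble(arrow::read_parquet(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  as_feature_table(raw, na_action = match.arg(na_action))
}

#' @rdname read_feature_table
#' @param table A feature table (validated on write).
#' @return `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path, format = c("auto", "csv", "parquet")) {
  if (nrow(table) == 0L) {
    rs_abort("refusing to write an empty feature table", "radshap_table_error")
  }
  table <- as_feature_table(table)
  format <- table_format(path, match.arg(format))
  if (format == "parquet") {
    arrow::write_parquet(as_tibble(unclass0(table)), path)
  } else {
    # readr writes doubles with full round-trip precision by default
    readr::write_csv(as_tibble(unclass0(table)), path, progress = FALSE)
  }
  invisible(path)
}

unclass0 <- function(x) {
  class(x) <- setdiff(class(x), "radshap_table")
  x
}

#' @export
print.radshap_table <- function(x, ...) {
  nf <- length(feature_cols(x))
  cat(sprintf(
    "# Radiomic feature table: %d slices, %d patients, %d features\n",
    nrow(x), dplyr::n_distinct(x$patient_id), nf
  ))
  cat(sprintf(
    "# Class counts (minimal..marked): %s\n",
    paste(tabulate(x$label, 4L), collapse = "/")
  ))
  NextMethod()
}
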