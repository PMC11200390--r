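#' Patient-stratified train/validation/test split
#'
#' Assigns whole patients to train/validation/test so that set sizes hit the
#' target slice fractions (default 62/19/19) within a tolerance and every
#' class holds at least `min_fraction` of each set's slices. The split is
#' found by rejection sampling: patients are randomly permuted, each is packed
#' greedily into the set currently furthest below its target fraction, and the
#' candidate is accepted only if every constraint holds; otherwise a new
#' permutation is drawn, up to `max_attempts`. Constraints are never silently
#' relaxed — infeasibility raises an error naming the tightest violated
#' constraint.
#'
#' @param table A `radshap_table`.
#' @param fractions Named numeric target slice fractions for train, val, test
#'   (sums to 1).
#' @param min_fraction Minimum per-class share of each set's slices.
#' @param tolerance Allowed absolute deviation of realised set fractions from
#'   targets.
#' @param seed Integer seed (assignment is deterministic given it).
#' @param max_attempts Rejection-sampling budget.
#' @return A `radshap_split` tibble mapping `slice_id`/`patient_id` to `set`
#'   (factor train/val/test); CV folds, when added, live in attribute
#'   `"cv_folds"`.
#' @export
stratified_split <- function(table,
                             fractions = c(train = 0.62, val = 0.19, test = 0.19),
                             min_fraction = 0.10,
                             tolerance = 0.05,
                             seed = 1L,
                             max_attempts = 10000L) {
  stopifnot(inherits(table, "radshap_table"))
  if (abs(sum(fractions) - 1) > 1e-8 ||
    !setequal(names(fractions), c("train", "val", "test"))) {
    rs_abort("fractions must be named train/val/test and sum to 1",
      "radshap_split_error")
  }
  fractions <- fractions[c("train", "val", "test")]
  pat <- table %>%
    group_by(.data$patient_id) %>%
    summarise(n_slices = n(), label = .data$label[1], .groups = "drop")
  if (nrow(pat) < 3L) {
    rs_abort("need at least 3 patients to split", "radshap_split_error")
  }
  if (!all(1:4 %in% table$label)) {
    rs_abort("all four classes must be present before splitting",
      "radshap_split_error")
  }
  n_total <- nrow(table)
  sets <- names(fractions)

  worst <- NULL # diagnostics from the best failed attempt
  result <- with_seed(seed, {
    found <- NULL
    for (attempt in seq_len(max_attempts)) {
      ord <- sample.int(nrow(pat))
      assign_set <- character(nrow(pat))
      set_n <- setNames(numeric(3), sets)
      for (i in ord) {
        # pack into the set furthest below its target share
        deficit <- fractions - set_n / n_total
        pick <- sets[which.max(deficit)]
        assign_set[i] <- pick
        set_n[pick] <- set_n[pick] + pat$n_slices[i]
      }
      viol <- split_violations(pat, assign_set, fractions, min_fraction,
        tolerance, n_total)
      if (nrow(viol) == 0L) {
        found <- tibble(patient_id = pat$patient_id, set = assign_set)
        break
      }
      if (is.null(worst) || max(viol$gap) < max(worst$gap)) worst <- viol
    }
    found
  })
  if (is.null(result)) {
    top <- worst[which.max(worst$gap), ]
    rs_abort(
      paste0(
        "no feasible split in ", max_attempts, " attempts; tightest violated ",
        "constraint: ", top$constraint, " (shortfall ",
        sprintf("%.3f", top$gap), ")"
      ),
      "radshap_split_infeasible"
    )
  }
  out <- table %>%
    select("slice_id", "patient_id", "label") %>%
    left_join(result, by = "patient_id") %>%
    mutate(set = factor(.data$set, levels = sets))
  class(out) <- c("radshap_split", class(out))
  out
}

split_violations <- function(pat, assign_set, fractions, min_fraction,
                             tolerance, n_total) {
  out <- list()
  for (s in names(fractions)) {
    idx <- assign_set == s
    ns <- sum(pat$n_slices[idx])
    dev <- abs(ns / n_total - fractions[[s]])
    if (dev > tolerance) {
      out[[length(out) + 1L]] <- tibble(
        constraint = paste0("set '", s, "' slice fraction within ",
          tolerance, " of ", fractions[[s]]),
        gap = dev - tolerance
      )
    }
    if (ns == 0) {
      out[[length(out) + 1L]] <- tibble(
        constraint = paste0("set '", s, "' non-empty"), gap = 1
      )
      next
    }
    cls_n <- vapply(1:4, function(k) sum(pat$n_slices[idx & pat$label == k]),
      numeric(1))
    short <- min_fraction - cls_n / ns
    if (any(short > 0)) {
      k <- which.max(short)
      out[[length(out) + 1L]] <- tibble(
        constraint = paste0("class ", k, " >= ", min_fraction,
          " of set '", s, "'"),
        gap = max(short)
      )
    }
  }
  if (length(out) == 0L) tibble(constraint = character(), gap = numeric()) else bind_rows(out)
}

#' Add 5-fold cross-validation folds over the non-test patients
#'
#' Partitions the non-test patients into `k` folds (each fold's patients form
#' one validation set, the remainder the training set) such that every class
#' holds at least `cv_min_fraction` of the slices of every fold's train and
#' validation parts. Found by rejection sampling like [stratified_split()].
#'
#' @param table A `radshap_table`.
#' @param assignment A `radshap_split` from [stratified_split()].
#' @param k Number of folds.
#' @param cv_min_fraction Per-class minimum slice share within each fold part.
#' @inheritParams stratified_split
#' @return The assignment with attribute `"cv_folds"`: a tibble of
#'   `patient_id`, `fold` (1..k; validation fold of that patient).
#' @export
make_cv_folds <- function(table, assignment, k = 5L, cv_min_fraction = 0.02,
                          seed = 1L, max_attempts = 10000L) {
  stopifnot(inherits(assignment, "radshap_split"))
  pool <- assignment %>%
    filter(.data$set != "test") %>%
    group_by(.data$patient_id) %>%
    summarise(n_slices = n(), label = .data$label[1], .groups = "drop")
  if (nrow(pool) < k) {
    rs_abort("fewer non-test patients than folds", "radshap_split_infeasible")
  }
  folds <- with_seed(seed, {
    found <- NULL
    for (attempt in seq_len(max_attempts)) {
      # class-stratified dealing: patients shuffled within class, classes in
      # random order, one fold pointer rotating across the whole sequence —
      # rare classes spread over folds and fold sizes stay within +-1
      ord <- unlist(lapply(sample(unique(pool$label)), function(cl) {
        idx <- which(pool$label == cl)
        if (length(idx) > 1L) sample(idx) else idx
      }))
      fold_of <- integer(nrow(pool))
      fold_of[ord] <- (sample.int(k, 1L) + seq_along(ord) - 1L) %% k + 1L
      ok <- TRUE
      for (f in seq_len(k)) {
        for (part in list(fold_of == f, fold_of != f)) {
          ns <- sum(pool$n_slices[part])
          if (ns == 0) {
            ok <- FALSE
            break
          }
          cls_n <- vapply(1:4, function(cl) {
            sum(pool$n_slices[part & pool$label == cl])
          }, numeric(1))
          if (any(cls_n / ns < cv_min_fraction)) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) {
        found <- tibble(patient_id = pool$patient_id, fold = fold_of)
        break
      }
    }
    found
  })
  if (is.null(folds)) {
    rs_abort(
      paste0("no feasible ", k, "-fold partition in ", max_attempts,
        " attempts (class representation >= ", cv_min_fraction, ")"),
      "radshap_split_infeasible"
    )
  }
  attr(assignment, "cv_folds") <- folds
  assignment
}

#' Split a feature table by an assignment
#'
#' @param table A `radshap_table`.
#' @param assignment A `radshap_split`.
#' @param set One of `"train"`, `"val"`, `"test"`.
#' @return The subset of `table` in that set, as a `radshap_table`.
#' @export
split_subset <- function(table, assignment, set = c("train", "val", "test")) {
  set <- match.arg(set)
  ids <- assignment$slice_id[assignment$set == set]
  as_feature_table(table[table$slice_id %in% ids, ])
}

#' @rdname stratified_split
#' @param x A `radshap_split`.
#' @param path JSON output path.
#' @export
write_split <- function(x, path) {
  stopifnot(inherits(x, "radshap_split"))
  payload <- list(
    slices = lapply(seq_len(nrow(x)), function(i) {
      list(slice_id = x$slice_id[i], patient_id = x$patient_id[i],
        set = as.character(x$set[i]))
    }),
    cv_folds = if (!is.null(attr(x, "cv_folds"))) {
      f <- attr(x, "cv_folds")
      lapply(seq_len(nrow(f)), function(i) {
        list(patient_id = f$patient_id[i], fold = f$fold[i])
      })
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname stratified_split
#' @export
read_split <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as_tibble(raw$slices) %>%
    mutate(
      set = factor(.data$set, levels = c("train", "val", "test")),
      label = NA_integer_
    ) %>%
    select("slice_id", "patient_id", "label", "set")
  if (!is.null(raw$cv_folds) && length(raw$cv_folds) > 0) {
    attr(out, "cv_folds") <- as_tibble(raw$cv_folds)
  }
  class(out) <- c("radshap_split", class(out))
  out
}
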