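#' Select classes with sufficient support
#'
#' Returns the diagnosis classes whose record count reaches
#' `min_class_size`, in descending count order (ties broken by code).
#' Applied to the thyroid panel's class distribution with the default
#' threshold of 200, this selects the five classes used for balanced
#' modelling: no condition, concurrent non-thyroidal illness, compensated
#' hypothyroid, increased binding protein and primary hypothyroid.
#'
#' @param x a [cohort()].
#' @param min_class_size minimum record count (default 200).
#' @return Character vector of class codes (possibly empty).
#' @export
select_classes <- function(x, min_class_size = 200L) {
  stopifnot(inherits(x, "cohort"), min_class_size >= 1)
  cc <- class_counts(x)
  names(cc)[cc >= min_class_size]
}

#' Down-sample a cohort by keeping the first n records of each class
#'
#' For every selected class, exactly the first `n` of its records in
#' original file order are kept; records of unselected classes are dropped.
#' The overall relative order of kept rows is preserved and the procedure
#' involves no randomness. A class with fewer than `n` records is an error
#' unless `allow_short` is set, in which case all of its records are kept
#' and a warning is issued.
#'
#' @param x a [cohort()].
#' @param classes character vector of class codes to keep.
#' @param n records to keep per class (default 230).
#' @param allow_short keep all records of a class with fewer than `n`
#'   instead of erroring (logged via warning).
#' @return A list with elements `cohort` (the balanced cohort) and `plan`
#'   (a `balance_plan`: selected classes, kept row indices per class, and
#'   dropped classes).
#' @export
downsample_first_n <- function(x, classes, n = 230L, allow_short = FALSE) {
  stopifnot(inherits(x, "cohort"), length(classes) >= 1, n >= 1)
  lab <- cohort_labels(x)
  kept <- list()
  for (cl in classes) {
    idx <- which(lab == cl)
    if (length(idx) < n) {
      if (!allow_short)
        stop(sprintf("class '%s' has %d record(s), fewer than n = %d",
                     cl, length(idx), n), call. = FALSE)
      warning(sprintf("class '%s' kept short: %d < %d", cl, length(idx), n),
              call. = FALSE)
      kept[[cl]] <- idx
    } else {
      kept[[cl]] <- idx[seq_len(n)]
    }
  }
  all_idx <- sort(unlist(kept, use.names = FALSE))
  dropped <- setdiff(unique(lab), classes)
  out <- cohort(x$data[all_idx, , drop = FALSE], x$schema)
  plan <- structure(list(selected_classes = classes,
                         kept_indices = kept,
                         per_class_n = as.integer(n),
                         dropped_classes = dropped),
                    class = "balance_plan")
  list(cohort = out, plan = plan)
}

#' @export
print.balance_plan <- function(x, ...) {
  cat(sprintf("<balance_plan> %d class(es) kept at %d record(s) each; %d class(es) dropped\n",
              length(x$selected_classes), x$per_class_n,
              length(x$dropped_classes)))
  invisible(x)
}

#' Balance a cohort in one step
#'
#' Convenience wrapper: [select_classes()] with `min_class_size`, then
#' [downsample_first_n()] with `per_class_n`.
#'
#' @param x a [cohort()].
#' @param min_class_size class-selection threshold (default 200).
#' @param per_class_n records kept per selected class (default 230).
#' @param allow_short see [downsample_first_n()].
#' @return As [downsample_first_n()].
#' @export
balance_cohort <- function(x, min_class_size = 200L, per_class_n = 230L,
                           allow_short = FALSE) {
  sel <- select_classes(x, min_class_size)
  if (!length(sel))
    stop("no class reaches min_class_size = ", min_class_size, call. = FALSE)
  downsample_first_n(x, sel, per_class_n, allow_short)
}
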