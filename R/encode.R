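#' Encoding policy for raw cohorts
#'
#' Controls how a raw character cohort becomes a numeric matrix: which tokens
#' count as binary true/false, whether constant columns are dropped, and an
#' optional explicit drop list (e.g. to discard the mostly-missing TBG
#' column).
#'
#' @param true_tokens tokens mapped to 1 in binary columns.
#' @param false_tokens tokens mapped to 0 in binary columns.
#' @param drop_constant drop feature columns that are constant after
#'   imputation (they carry no information for any classifier).
#' @param drop_columns character vector of feature column names to drop
#'   before encoding.
#' @return An object of class `encoding_policy`.
#' @export
encoding_policy <- function(true_tokens = c("t", "T", "y", "F"),
                            false_tokens = c("f", "n", "M"),
                            drop_constant = TRUE,
                            drop_columns = character(0)) {
  structure(list(true_tokens = true_tokens, false_tokens = false_tokens,
                 drop_constant = drop_constant, drop_columns = drop_columns),
            class = "encoding_policy")
}

#' Numerically encode a cohort for model fitting
#'
#' Produces a fully numeric feature matrix and integer class labels:
#' * binary columns map true/false tokens (`t`/`f`, and `F`/`M` for sex) to
#'   1/0, with missing entries imputed by the column mode;
#' * continuous columns are parsed as numbers, with missing entries imputed
#'   by the column median;
#' * categorical columns are integer-coded by first-appearance order, missing
#'   entries imputed by the column mode;
#' * identifier columns are dropped; constant columns are dropped when the
#'   policy says so (recorded in attribute `"dropped_constant"`).
#'
#' Multi-label records are excluded first (via [filter_single_label()]).
#' The class map is the sorted set of diagnosis codes present in the cohort;
#' labels are integer indices `1..C` into it.
#'
#' @param x a [cohort()].
#' @param policy an [encoding_policy()].
#' @return An object of class `encoded_matrix` with elements `X` (numeric
#'   matrix), `y` (integer labels), `class_map` (ordered code vector) and
#'   `feature_names`.
#' @export
encode_features <- function(x, policy = encoding_policy()) {
  stopifnot(inherits(x, "cohort"), inherits(policy, "encoding_policy"))
  x <- filter_single_label(x)
  df <- x$data
  sc <- x$schema$columns
  miss <- x$schema$missing_token
  lab <- cohort_labels(x)
  class_map <- sort(unique(lab), method = "radix")
  y <- match(lab, class_map)

  cols <- list()
  for (i in seq_len(nrow(sc))) {
    nmi <- sc$name[i]; kind <- sc$kind[i]
    if (kind %in% c("identifier", "target")) next
    if (nmi %in% policy$drop_columns) next
    v <- df[[nmi]]
    is_na <- v == miss | is.na(v)
    if (all(is_na))
      stop("column '", nmi, "' is entirely missing; nothing to impute from",
           call. = FALSE)
    num <- rep(NA_real_, length(v))
    if (kind == "binary") {
      num[!is_na & v %in% policy$true_tokens] <- 1
      num[!is_na & v %in% policy$false_tokens] <- 0
      bad <- !is_na & is.na(num)
      if (any(bad))
        stop("unknown token(s) in binary column '", nmi, "': ",
             paste(unique(v[bad]), collapse = ", "), call. = FALSE)
      num[is_na] <- mode_value(num[!is_na])
    } else if (kind == "continuous") {
      parsed <- suppressWarnings(as.numeric(v[!is_na]))
      if (anyNA(parsed))
        stop("non-numeric value(s) in continuous column '", nmi, "'",
             call. = FALSE)
      num[!is_na] <- parsed
      num[is_na] <- stats::median(parsed)
    } else { # categorical: first-appearance integer coding
      levs <- unique(v[!is_na])
      num[!is_na] <- match(v[!is_na], levs)
      num[is_na] <- mode_value(num[!is_na])
    }
    cols[[nmi]] <- num
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  dropped <- character(0)
  if (policy$drop_constant && ncol(X) > 0) {
    const <- apply(X, 2, function(c) length(unique(c)) == 1L)
    dropped <- colnames(X)[const]
    X <- X[, !const, drop = FALSE]
  }
  out <- encoded_matrix(X, y, class_map)
  attr(out, "dropped_constant") <- dropped
  attr(out, "excluded_multilabel") <- attr(x, "excluded_multilabel")
  out
}

# modal value; ties broken by the smaller value for determinism
mode_value <- function(v) {
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])
}

#' Construct an encoded matrix
#'
#' @param X numeric feature matrix (n x p) with no missing values.
#' @param y integer class labels in `1..length(class_map)`.
#' @param class_map ordered character vector mapping label index to class
#'   code.
#' @return An object of class `encoded_matrix`.
#' @export
encoded_matrix <- function(X, y, class_map) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), !anyNA(X),
            all(y >= 1L & y <= length(class_map)))
  structure(list(X = X, y = y, class_map = as.character(class_map),
                 feature_names = colnames(X)),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("<encoded_matrix> %d x %d; %d classes (%s)\n",
              nrow(x$X), ncol(x$X), length(x$class_map),
              paste(x$class_map, collapse = ", ")))
  invisible(x)
}

subset_encoded <- function(em, idx) {
  encoded_matrix(em$X[idx, , drop = FALSE], em$y[idx], em$class_map)
}

#' Split an encoded matrix into train and test partitions
#'
#' The test partition holds `round(ratio * n)` rows. Without shuffling, the
#' test set is the tail of the data in row order; with shuffling, row order
#' is first permuted by a seeded generator and the tail of the permuted order
#' is taken. The split is deterministic given the seed and is not stratified
#' by class.
#'
#' @param data an `encoded_matrix`.
#' @param ratio test fraction in (0, 1); default 0.2 for an 80:20 split.
#' @param seed integer seed for the permutation.
#' @param shuffle permute rows before cutting (default TRUE).
#' @return An object of class `split_pair` with elements `train`, `test`,
#'   `ratio`, `seed`, `shuffled`, and the row indices of each partition.
#' @export
split_train_test <- function(data, ratio = 0.2, seed = 1L, shuffle = TRUE) {
  stopifnot(inherits(data, "encoded_matrix"), ratio > 0, ratio < 1)
  n <- nrow(data$X)
  if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
  n_test <- round(ratio * n)
  if (n_test < 1 || n_test >= n)
    stop("ratio ", ratio, " yields an empty partition for n = ", n,
         call. = FALSE)
  ord <- if (shuffle) {
    withr::with_seed(seed, sample.int(n),
                     .rng_kind = "Mersenne-Twister",
                     .rng_sample_kind = "Rejection")
  } else seq_len(n)
  test_idx <- ord[(n - n_test + 1L):n]
  train_idx <- ord[seq_len(n - n_test)]
  structure(list(train = subset_encoded(data, train_idx),
                 test = subset_encoded(data, test_idx),
                 train_idx = train_idx, test_idx = test_idx,
                 ratio = ratio, seed = as.integer(seed),
                 shuffled = isTRUE(shuffle)),
            class = "split_pair")
}

#' @export
print.split_pair <- function(x, ...) {
  cat(sprintf("<split_pair> train %d / test %d (ratio %.2f, seed %d%s)\n",
              nrow(x$train$X), nrow(x$test$X), x$ratio, x$seed,
              if (x$shuffled) ", shuffled" else ""))
  invisible(x)
}
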