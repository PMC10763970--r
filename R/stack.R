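#' Configure a self-stacking classifier
#'
#' Self-stacking combines `m` homogeneous base learners (by default four
#' random forests differing only in their derived seeds) with a meta-learner
#' of the same family. The meta-learner is trained on out-of-fold base
#' predictions so it never sees a base model's fit to a row that model was
#' trained on.
#'
#' @param m number of base learners (default 4).
#' @param k folds used to construct out-of-fold meta-features (default 5).
#' @param meta_mode `"label"` (base learners contribute their predicted
#'   class, one-hot encoded for the meta-learner) or `"proba"` (full
#'   class-probability vectors).
#' @param base_spec [learner_spec()] for the base learners; each learner `j`
#'   is fit with seed `master_seed + j`.
#' @param meta_spec [learner_spec()] for the meta-learner, fit with
#'   `master_seed`.
#' @param master_seed integer seed controlling folds and all derived seeds.
#' @return An object of class `stack_config`.
#' @export
stack_config <- function(m = 4L, k = 5L,
                         meta_mode = c("label", "proba"),
                         base_spec = learner_spec("rf"),
                         meta_spec = learner_spec("rf"),
                         master_seed = 42L) {
  meta_mode <- match.arg(meta_mode)
  stopifnot(m >= 1, k >= 2,
            inherits(base_spec, "learner_spec"),
            inherits(meta_spec, "learner_spec"))
  structure(list(m = as.integer(m), k = as.integer(k),
                 meta_mode = meta_mode, base_spec = base_spec,
                 meta_spec = meta_spec,
                 master_seed = as.integer(master_seed)),
            class = "stack_config")
}

derive_spec <- function(spec, seed) {
  spec$seed <- as.integer(seed)
  spec
}

stack_folds <- function(n, k, master_seed) {
  withr::with_seed(master_seed, sample(rep_len(seq_len(k), n)),
                   .rng_kind = "Mersenne-Twister",
                   .rng_sample_kind = "Rejection")
}

#' Build out-of-fold meta-features
#'
#' For each base learner `j` and each of `k` folds, learner `j` (seeded
#' `master_seed + j`) is fit on the fold's complement and predicts the
#' held-out fold. Row `i`'s meta-feature for learner `j` is therefore always
#' an out-of-fold prediction: no entry of `Z` was produced by a model that
#' saw that row during training.
#'
#' @param train an [encoded_matrix()].
#' @param config a [stack_config()].
#' @return An object of class `meta_dataset` with elements `Z` (n x m label
#'   matrix in label mode; n x (m*C) probability matrix in proba mode), `y`,
#'   `fold_assignment`, `mode`, `m` and `n_classes`.
#' @export
build_meta_features <- function(train, config) {
  stopifnot(inherits(train, "encoded_matrix"),
            inherits(config, "stack_config"))
  n <- nrow(train$X)
  if (n == 0) stop("empty training set", call. = FALSE)
  k <- config$k
  if (k > n) stop("k = ", k, " exceeds n = ", n, call. = FALSE)
  C <- length(train$class_map)
  folds <- stack_folds(n, k, config$master_seed)
  m <- config$m
  Z <- if (config$meta_mode == "label") {
    matrix(NA_integer_, n, m,
           dimnames = list(NULL, paste0("base", seq_len(m))))
  } else {
    matrix(NA_real_, n, m * C,
           dimnames = list(NULL, paste0("base", rep(seq_len(m), each = C),
                                        "_c", rep(seq_len(C), m))))
  }
  for (f in seq_len(k)) {
    hold <- folds == f
    y_fit <- train$y[!hold]
    if (length(setdiff(seq_len(C), unique(y_fit))))
      warning("fold ", f, " training complement is missing ",
              "class(es); absent classes predicted with probability 0",
              call. = FALSE)
    for (j in seq_len(m)) {
      spec_j <- derive_spec(config$base_spec, config$master_seed + j)
      fit <- fit_learner(spec_j, train$X[!hold, , drop = FALSE], y_fit, C)
      if (config$meta_mode == "label") {
        Z[hold, j] <- predict(fit, train$X[hold, , drop = FALSE],
                              type = "label")
      } else {
        Z[hold, (j - 1L) * C + seq_len(C)] <-
          predict(fit, train$X[hold, , drop = FALSE], type = "prob")
      }
    }
  }
  structure(list(Z = Z, y = train$y, fold_assignment = folds,
                 mode = config$meta_mode, m = m, n_classes = C),
            class = "meta_dataset")
}

# encode meta-features for the meta-learner: label mode one-hot expands each
# base prediction to C indicator columns so no ordinal structure is invented
meta_design <- function(Z, mode, m, C) {
  if (mode == "proba") return(Z)
  n <- nrow(Z)
  D <- matrix(0, n, m * C,
              dimnames = list(NULL, paste0("base", rep(seq_len(m), each = C),
                                           "_c", rep(seq_len(C), m))))
  if (n)
    for (j in seq_len(m))
      D[cbind(seq_len(n), (j - 1L) * C + Z[, j])] <- 1
  D
}

#' Fit a self-stacking classifier
#'
#' Builds the out-of-fold meta-dataset, fits the meta-learner on it, then
#' refits each base learner on the full training set for inference.
#'
#' @param train an [encoded_matrix()].
#' @param config a [stack_config()].
#' @return An object of class `self_stack`.
#' @export
fit_self_stack <- function(train, config = stack_config()) {
  stopifnot(inherits(train, "encoded_matrix"))
  C <- length(train$class_map)
  if (length(unique(train$y)) < 2)
    stop("training data contain a single class; the meta-learner cannot be fit",
         call. = FALSE)
  meta <- build_meta_features(train, config)
  D <- meta_design(meta$Z, meta$mode, meta$m, C)
  meta_fit <- fit_learner(derive_spec(config$meta_spec, config$master_seed),
                          D, meta$y, C)
  base_fits <- lapply(seq_len(config$m), function(j) {
    fit_learner(derive_spec(config$base_spec, config$master_seed + j),
                train$X, train$y, C)
  })
  structure(list(base_models = base_fits, meta_model = meta_fit,
                 config = config, class_map = train$class_map,
                 n_classes = C, p = ncol(train$X),
                 meta_dataset = meta),
            class = "self_stack")
}

#' @export
print.self_stack <- function(x, ...) {
  cat(sprintf("<self_stack> %d x %s base learners + %s meta-learner (%s mode, k = %d)\n",
              x$config$m, x$config$base_spec$family,
              x$config$meta_spec$family, x$config$meta_mode, x$config$k))
  invisible(x)
}

#' Predict with a fitted self-stacking classifier
#'
#' Base models predict on `X`; their outputs are encoded exactly as at
#' meta-training time (one-hot labels or stacked probability blocks) and
#' passed to the meta-learner.
#'
#' @param object a `self_stack`.
#' @param X numeric feature matrix with the training column count.
#' @param ... unused.
#' @return Integer label vector (indices into `object$class_map`).
#' @export
predict.self_stack <- function(object, X, ...) {
  X <- as.matrix(X)
  if (nrow(X) && ncol(X) != object$p)
    stop("feature count mismatch: model expects ", object$p, " columns, got ",
         ncol(X), call. = FALSE)
  if (nrow(X) == 0) return(integer(0))
  C <- object$n_classes
  cfg <- object$config
  if (cfg$meta_mode == "label") {
    Z <- vapply(object$base_models, function(b) predict(b, X, "label"),
                integer(nrow(X)))
    Z <- matrix(Z, nrow(X), cfg$m)
  } else {
    Z <- do.call(cbind, lapply(object$base_models,
                               function(b) predict(b, X, "prob")))
  }
  D <- meta_design(Z, cfg$meta_mode, cfg$m, C)
  predict(object$meta_model, D, type = "label")
}
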