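#' Fit a model from any supported specification
#'
#' Uniform fitting entry point used by the cross-validation harness and the
#' experiment runner: dispatches on the specification class.
#'
#' @param spec a [learner_spec()], [stack_config()] or [vote_config()].
#' @param train an [encoded_matrix()].
#' @return A fitted model whose `predict` method returns integer labels.
#' @export
fit_model <- function(spec, train) UseMethod("fit_model")

#' @export
fit_model.learner_spec <- function(spec, train) {
  stopifnot(inherits(train, "encoded_matrix"))
  fit <- fit_learner(spec, train$X, train$y, length(train$class_map))
  fit$class_map <- train$class_map
  fit
}

#' @export
fit_model.stack_config <- function(spec, train) fit_self_stack(train, spec)

#' @export
fit_model.vote_config <- function(spec, train) {
  fit_self_vote(train, spec$n_base, spec$spec, spec$criterion,
                spec$master_seed)
}

#' k-fold cross-validation of a model specification
#'
#' Rows are assigned to `k` near-equal folds by a seeded shuffle (fold sizes
#' differ by at most one and cover every row exactly once). For each fold
#' the model is fit on the complement and scored on the fold; the summary
#' reports the per-fold accuracies, their mean, sample (n-1) standard
#' deviation, and wall time.
#'
#' @param model_spec a [learner_spec()], [stack_config()] or
#'   [vote_config()].
#' @param data an [encoded_matrix()].
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return An object of class `cv_result` with `fold_accuracies`,
#'   `mean_accuracy`, `sd`, `k`, `seed`, `elapsed_seconds`.
#' @export
kfold_cv <- function(model_spec, data, k = 10L, seed = 1L) {
  stopifnot(inherits(data, "encoded_matrix"), k >= 2)
  n <- nrow(data$X)
  if (k > n) stop("k = ", k, " exceeds n = ", n, call. = FALSE)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)),
                            .rng_kind = "Mersenne-Twister",
                            .rng_sample_kind = "Rejection")
  t0 <- proc.time()[["elapsed"]]
  acc <- vapply(seq_len(k), function(f) {
    hold <- folds == f
    fit <- fit_model(model_spec, subset_encoded(data, which(!hold)))
    pred <- predict(fit, data$X[hold, , drop = FALSE])
    mean(pred == data$y[hold])
  }, numeric(1))
  structure(list(fold_accuracies = acc,
                 mean_accuracy = mean(acc),
                 sd = stats::sd(acc),
                 k = as.integer(k), seed = as.integer(seed),
                 fold_assignment = folds,
                 elapsed_seconds = proc.time()[["elapsed"]] - t0),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold: accuracy %.3f +/- %.3f (%.1fs)\n",
              x$k, x$mean_accuracy, x$sd, x$elapsed_seconds))
  invisible(x)
}
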