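#' Hard (majority) vote over member label predictions
#'
#' Per sample, returns the modal label across ensemble members; ties break
#' to the lowest class index. Pure function of the prediction matrix.
#'
#' @param predictions integer matrix, `n_members` rows x `n_samples`
#'   columns, of class indices.
#' @param n_classes size of the class index space (defaults to the largest
#'   label present).
#' @return Integer label vector of length `n_samples`.
#' @export
vote_hard <- function(predictions, n_classes = max(predictions)) {
  predictions <- as.matrix(predictions)
  if (length(predictions) == 0)
    stop("empty prediction matrix", call. = FALSE)
  storage.mode(predictions) <- "integer"
  apply(predictions, 2, function(col) which.max(tabulate(col, n_classes)))
}

#' Soft vote over member class probabilities
#'
#' Per sample, sums the members' probability vectors and returns the argmax;
#' ties break to the lowest class index. Each member's row must lie on the
#' probability simplex (sum to 1 within 1e-6).
#'
#' @param probabilities numeric array `n_members x n_samples x n_classes`.
#' @return Integer label vector of length `n_samples`.
#' @export
vote_soft <- function(probabilities) {
  stopifnot(is.array(probabilities), length(dim(probabilities)) == 3)
  sums <- apply(probabilities, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("probability rows must sum to 1 (tolerance 1e-6)", call. = FALSE)
  total <- apply(probabilities, c(2, 3), sum)
  apply(total, 1, which.max)
}

#' Configure a self-voting ensemble
#'
#' @param n_base number of members (default 3).
#' @param spec [learner_spec()] for every member; member `j` is fit with
#'   seed `master_seed + j`.
#' @param criterion `"hard"` (majority vote on labels) or `"soft"` (argmax
#'   of summed probabilities).
#' @param master_seed integer seed.
#' @return An object of class `vote_config`.
#' @export
vote_config <- function(n_base = 3L, spec = learner_spec("rf"),
                        criterion = c("hard", "soft"),
                        master_seed = 42L) {
  criterion <- match.arg(criterion)
  stopifnot(n_base >= 1, inherits(spec, "learner_spec"))
  structure(list(n_base = as.integer(n_base), spec = spec,
                 criterion = criterion,
                 master_seed = as.integer(master_seed)),
            class = "vote_config")
}

#' Fit a self-voting ensemble
#'
#' Fits `n_base` learners of the same family with distinct derived seeds
#' (`master_seed + j`); the voting criterion is fixed at fit time.
#'
#' @param train an [encoded_matrix()].
#' @param n_base number of members (default 3).
#' @param spec [learner_spec()] for the members.
#' @param criterion `"hard"` or `"soft"`.
#' @param master_seed integer seed.
#' @return An object of class `vote_ensemble`.
#' @export
fit_self_vote <- function(train, n_base = 3L, spec = learner_spec("rf"),
                          criterion = c("hard", "soft"),
                          master_seed = 42L) {
  stopifnot(inherits(train, "encoded_matrix"))
  criterion <- match.arg(criterion)
  C <- length(train$class_map)
  members <- lapply(seq_len(n_base), function(j) {
    fit_learner(derive_spec(spec, master_seed + j), train$X, train$y, C)
  })
  structure(list(base_models = members, criterion = criterion,
                 class_map = train$class_map, n_classes = C,
                 p = ncol(train$X),
                 master_seed = as.integer(master_seed)),
            class = "vote_ensemble")
}

#' @export
print.vote_ensemble <- function(x, ...) {
  cat(sprintf("<vote_ensemble> %d x %s members, %s voting\n",
              length(x$base_models), x$base_models[[1]]$spec$family,
              x$criterion))
  invisible(x)
}

#' Predict with a self-voting ensemble
#'
#' @param object a `vote_ensemble`.
#' @param X numeric feature matrix with the training column count.
#' @param ... unused.
#' @return Integer label vector.
#' @export
predict.vote_ensemble <- function(object, X, ...) {
  X <- as.matrix(X)
  if (nrow(X) && ncol(X) != object$p)
    stop("feature count mismatch: model expects ", object$p, " columns, got ",
         ncol(X), call. = FALSE)
  if (nrow(X) == 0) return(integer(0))
  C <- object$n_classes
  B <- length(object$base_models)
  if (object$criterion == "hard") {
    preds <- t(vapply(object$base_models,
                      function(b) predict(b, X, "label"),
                      integer(nrow(X))))
    vote_hard(matrix(preds, B, nrow(X)), C)
  } else {
    arr <- array(NA_real_, c(B, nrow(X), C))
    for (j in seq_len(B))
      arr[j, , ] <- predict(object$base_models[[j]], X, "prob")
    vote_soft(arr)
  }
}
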