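#' Specify a base learner
#'
#' A learner spec names a model family, its hyperparameters and a seed.
#' Defaults reproduce the tuned settings used throughout the package's
#' evaluation protocol:
#' * `rf`: random forest, 200 trees, depth cap 50 (via \pkg{ranger},
#'   probability forest);
#' * `gbm`: gradient boosting, 50 rounds, learning rate 0.2, depth cap 200
#'   (via \pkg{xgboost});
#' * `adaboost`: multi-class SAMME boosting of decision stumps, 300
#'   estimators, learning rate 0.8 (implemented in-package on \pkg{rpart});
#' * `lr`: multinomial logistic regression, inverse regularization `C = 3`
#'   (via \pkg{nnet});
#' * `svc`: linear support vector classifier, `C = 1` (via \pkg{e1071}).
#'
#' Three deterministic stub families support testing: `constant` (always
#' predicts a fixed class, by default the training majority), `memorize`
#' (predicts the stored training label for rows it has seen and a
#' pseudo-random label otherwise — useful as a leakage detector) and
#' `argmax` (predicts the argmax position of each feature row, reduced
#' modulo the class count).
#'
#' @param family one of `"rf"`, `"gbm"`, `"adaboost"`, `"lr"`, `"svc"`,
#'   `"constant"`, `"memorize"`, `"argmax"`.
#' @param params named list of hyperparameter overrides; unknown names are
#'   an error.
#' @param seed integer seed; family defaults follow the tuned settings
#'   (52 for `gbm`, 5 for `adaboost`, 1 otherwise).
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(family, params = list(), seed = NULL) {
  defaults <- list(
    rf       = list(n_estimators = 200L, max_depth = 50L),
    gbm      = list(n_estimators = 50L, learning_rate = 0.2,
                    max_depth = 200L),
    adaboost = list(n_estimators = 300L, learning_rate = 0.8,
                    max_depth = 1L),
    lr       = list(C = 3.0, max_iter = 200L),
    svc      = list(kernel = "linear", C = 1.0),
    constant = list(value = NULL),
    memorize = list(),
    argmax   = list())
  if (length(family) != 1L || !family %in% names(defaults))
    stop("unknown learner family: ", paste(family, collapse = ", "),
         call. = FALSE)
  p <- defaults[[family]]
  unknown <- setdiff(names(params), names(p))
  if (length(unknown))
    stop("unknown hyperparameter(s) for '", family, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  p[names(params)] <- params
  if (is.null(seed))
    seed <- switch(family, gbm = 52L, adaboost = 5L, 1L)
  structure(list(family = family, params = p, seed = as.integer(seed)),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  ps <- paste(names(x$params),
              vapply(x$params, function(v) paste(format(v), collapse = "/"),
                     ""),
              sep = "=", collapse = ", ")
  cat(sprintf("<learner_spec> %s(%s), seed %d\n", x$family, ps, x$seed))
  invisible(x)
}

with_spec_seed <- function(spec, code) {
  withr::with_seed(spec$seed, code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_sample_kind = "Rejection")
}

#' Fit a learner on a numeric matrix
#'
#' @param spec a [learner_spec()].
#' @param X numeric feature matrix.
#' @param y integer class labels in `1..n_classes`.
#' @param n_classes number of classes in the label space (defaults to
#'   `max(y)`); classes absent from `y` get zero predicted probability.
#' @return An object of class `fitted_learner`.
#' @export
fit_learner <- function(spec, X, y, n_classes = max(y)) {
  stopifnot(inherits(spec, "learner_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), length(y) >= 1)
  n_classes <- as.integer(n_classes)
  p <- spec$params
  fy <- factor(y, levels = seq_len(n_classes))
  model <- switch(
    spec$family,
    rf = {
      d <- as.data.frame(X)
      d$.y <- droplevels(fy)
      ranger::ranger(dependent.variable.name = ".y", data = d,
                     num.trees = p$n_estimators, max.depth = p$max_depth,
                     probability = TRUE, seed = spec$seed, num.threads = 1L)
    },
    gbm = with_spec_seed(spec, {
      dtr <- xgboost::xgb.DMatrix(X, label = y - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = n_classes,
                      max_depth = p$max_depth, eta = p$learning_rate,
                      nthread = 1L, seed = spec$seed),
        data = dtr, nrounds = p$n_estimators, verbose = 0)
    }),
    adaboost = fit_samme(X, y, n_classes, p$n_estimators, p$learning_rate,
                         p$max_depth),
    lr = with_spec_seed(spec, {
      d <- as.data.frame(X)
      d$.y <- droplevels(fy)
      nnet::multinom(.y ~ ., data = d, decay = 1 / p$C,
                     maxit = p$max_iter, trace = FALSE,
                     MaxNWts = 100000L)
    }),
    svc = with_spec_seed(spec, {
      e1071::svm(X, droplevels(fy), kernel = p$kernel, cost = p$C,
                 probability = TRUE)
    }),
    constant = {
      v <- p$value
      if (is.null(v)) v <- which.max(tabulate(y, n_classes))
      list(value = as.integer(v))
    },
    memorize = list(keys = row_keys(X), y = y),
    argmax = list())
  structure(list(spec = spec, model = model, n_classes = n_classes,
                 p = ncol(X), seen_levels = sort(unique(y))),
            class = "fitted_learner")
}

row_keys <- function(X) {
  apply(X, 1, function(r) paste(format(r, digits = 12), collapse = "|"))
}

#' Predict with a fitted learner
#'
#' @param object a `fitted_learner`.
#' @param X numeric feature matrix with the training column count.
#' @param type `"label"` for integer class labels (probability argmax, ties
#'   to the lowest class index) or `"prob"` for an n x C probability matrix.
#' @param ... unused.
#' @return Integer vector or probability matrix.
#' @export
predict.fitted_learner <- function(object, X, type = c("label", "prob"),
                                   ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != object$p)
    stop("feature count mismatch: model expects ", object$p, " columns, got ",
         ncol(X), call. = FALSE)
  C <- object$n_classes
  if (nrow(X) == 0) {
    return(if (type == "label") integer(0) else
             matrix(numeric(0), 0, C))
  }
  pr <- learner_proba(object, X)
  if (type == "prob") return(pr)
  apply(pr, 1, which.max)
}

# full n x C probability matrix, zero-padding classes unseen in training
learner_proba <- function(object, X) {
  C <- object$n_classes
  spec <- object$spec
  m <- object$model
  out <- matrix(0, nrow(X), C)
  fill <- function(pr) {
    # pr has columns named by class index
    idx <- as.integer(colnames(pr))
    out[, idx] <- as.matrix(pr)
    out
  }
  switch(
    spec$family,
    rf = {
      pr <- stats::predict(m, as.data.frame(X), num.threads = 1L)$predictions
      fill(pr)
    },
    gbm = {
      pr <- stats::predict(m, xgboost::xgb.DMatrix(X))
      if (is.matrix(pr)) unname(pr) else matrix(pr, nrow(X), C, byrow = TRUE)
    },
    adaboost = predict_samme(m, X, C),
    lr = {
      pr <- stats::predict(m, as.data.frame(X), type = "probs")
      if (is.null(dim(pr))) { # vector cases: 2 levels, or a single row
        pr <- if (length(m$lev) == 2L) cbind(1 - pr, pr) else matrix(pr, 1)
        colnames(pr) <- m$lev
      }
      fill(pr)
    },
    svc = {
      pr <- attr(stats::predict(m, X, probability = TRUE), "probabilities")
      fill(pr[, order(as.integer(colnames(pr))), drop = FALSE])
    },
    constant = {
      out[, m$value] <- 1
      out
    },
    memorize = {
      keys <- row_keys(X)
      hit <- match(keys, m$keys)
      lab <- ifelse(!is.na(hit), m$y[hit],
                    (seq_len(nrow(X)) * 2654435761) %% C + 1L)
      out[cbind(seq_len(nrow(X)), lab)] <- 1
      out
    },
    argmax = {
      lab <- (apply(X, 1, which.max) - 1L) %% C + 1L
      out[cbind(seq_len(nrow(X)), lab)] <- 1
      out
    })
}

# Multi-class AdaBoost (SAMME) over rpart stumps. Weighted classification
# trees are refit on reweighted data each round; a round with weighted error
# >= 1 - 1/C is discarded and boosting stops, a perfect round gets a large
# finite weight.
fit_samme <- function(X, y, C, n_estimators, learning_rate, max_depth) {
  n <- length(y)
  w <- rep(1 / n, n)
  d <- as.data.frame(X)
  d$.y <- factor(y, levels = seq_len(C))
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, xval = 0,
                               minsplit = 2, minbucket = 1)
  for (t in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                        control = ctrl)
    pred <- as.integer(stats::predict(fit, d, type = "class"))
    err <- sum(w * (pred != y))
    if (err >= 1 - 1 / C) break
    err <- max(err, 1e-10)
    alpha <- learning_rate * (log((1 - err) / err) + log(C - 1))
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

predict_samme <- function(m, X, C) {
  out <- matrix(0, nrow(X), C)
  if (!length(m$stumps)) {
    out[] <- 1 / C
    return(out)
  }
  d <- as.data.frame(X)
  for (t in seq_along(m$stumps)) {
    pred <- as.integer(stats::predict(m$stumps[[t]], d, type = "class"))
    out[cbind(seq_len(nrow(X)), pred)] <-
      out[cbind(seq_len(nrow(X)), pred)] + m$alphas[t]
  }
  sweep(out, 1, rowSums(out), "/")
}
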