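test_that("learner specs reproduce the tuned defaults and reject unknowns", {
  rf <- learner_spec("rf")
  expect_equal(rf$params$n_estimators, 200L)
  expect_equal(rf$params$max_depth, 50L)
  ada <- learner_spec("adaboost")
  expect_equal(ada$params$n_estimators, 300L)
  expect_equal(ada$params$learning_rate, 0.8)
  expect_equal(ada$seed, 5L)
  gbm <- learner_spec("gbm")
  expect_equal(gbm$params$learning_rate, 0.2)
  expect_equal(gbm$seed, 52L)
  expect_error(learner_spec("XGB"), "unknown learner family")
  expect_error(learner_spec("rf", list(bogus = 1)),
               "unknown hyperparameter")
})

test_that("every learner family separates well-separated Gaussians", {
  em <- make_blobs(150, C = 3, sep = 3, seed = 2)
  sp <- split_train_test(em, 0.2, seed = 2)
  for (fam in c("rf", "gbm", "adaboost", "lr", "svc")) {
    fit <- fit_learner(learner_spec(fam), sp$train$X, sp$train$y, 3)
    acc <- mean(predict(fit, sp$test$X) == sp$test$y)
    expect_gt(acc, 0.9, label = sprintf("%s accuracy (%.3f)", fam, acc))
    pr <- predict(fit, sp$test$X, type = "prob")
    expect_equal(dim(pr), c(nrow(sp$test$X), 3))
    expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("hard voting matches the brute-force mode oracle", {
  expect_equal(vote_hard(matrix(c(1, 1, 2), 3, 1)), 1L)
  expect_equal(vote_hard(matrix(c(1, 2, 3), 3, 1)), 1L) # tie -> lowest index
  withr::with_seed(7, {
    preds <- matrix(sample(1:4, 3 * 1000, TRUE), 3, 1000)
    got <- vote_hard(preds, 4)
    want <- vapply(seq_len(1000), function(i) brute_mode(preds[, i], 4L),
                   integer(1))
    expect_equal(got, want)
  })
  expect_error(vote_hard(matrix(integer(0), 0, 0)), "empty")
})

test_that("soft voting sums probabilities and breaks ties to lowest index", {
  arr <- array(c(0.6, 0.6, 0.2, 0.4, 0.4, 0.8), c(3, 1, 2))
  expect_equal(vote_soft(arr), 2L) # sums (1.4, 1.6)
  uni <- array(1 / 3, c(3, 2, 3))
  expect_equal(vote_soft(uni), c(1L, 1L))
  bad <- array(c(0.5, 0.2), c(1, 1, 2))
  expect_error(vote_soft(bad), "sum to 1")
  # argmax of summed probabilities against a per-sample oracle
  withr::with_seed(8, {
    raw <- array(rexp(3 * 500 * 4), c(3, 500, 4))
    for (j in 1:3) for (i in 1:500)
      raw[j, i, ] <- raw[j, i, ] / sum(raw[j, i, ])
    got <- vote_soft(raw)
    want <- vapply(seq_len(500), function(i) {
      s <- raw[1, i, ] + raw[2, i, ] + raw[3, i, ]
      which(s == max(s))[1]
    }, integer(1))
    expect_equal(got, want)
  })
})

test_that("soft voting equals hard voting on one-hot member outputs", {
  withr::with_seed(9, {
    labels <- matrix(sample(1:3, 3 * 200, TRUE), 3, 200)
    arr <- array(0, c(3, 200, 3))
    for (j in 1:3) for (i in 1:200) arr[j, i, labels[j, i]] <- 1
    expect_equal(vote_soft(arr), vote_hard(labels, 3))
  })
})

test_that("self-voting ensembles reduce and duplicate as expected", {
  em <- make_blobs(60, C = 2, sep = 3, seed = 4)
  one <- fit_self_vote(em, n_base = 1, criterion = "hard", master_seed = 3)
  single <- one$base_models[[1]]
  expect_equal(predict(one, em$X), unname(predict(single, em$X)))
  # identical members: the vote equals any one member
  three <- fit_self_vote(em, n_base = 3, criterion = "hard", master_seed = 3)
  three$base_models[[2]] <- three$base_models[[1]]
  three$base_models[[3]]  <- three$base_models[[1]]
  expect_equal(predict(three, em$X),
               unname(predict(three$base_models[[1]], em$X)))
})

test_that("meta-feature matrices have the contracted shapes", {
  em <- make_blobs(10, C = 5, sep = 3, seed = 5) # n = 50
  base <- learner_spec("constant", list(value = 2))
  lab <- build_meta_features(em, stack_config(m = 4, k = 5,
                                              base_spec = base))
  expect_equal(dim(lab$Z), c(50, 4))
  expect_true(all(lab$Z == 2))
  pro <- build_meta_features(em, stack_config(m = 4, k = 5,
                                              meta_mode = "proba",
                                              base_spec = base))
  expect_equal(dim(pro$Z), c(50, 20))
  expect_error(build_meta_features(em, stack_config(k = 51)), "exceeds")
})

test_that("out-of-fold construction admits no training-label leakage", {
  # the memorizing stub reproduces training labels perfectly for any row it
  # saw; feature-independent labels make any out-of-sample prediction chance
  withr::with_seed(10, {
    n <- 500
    X <- matrix(rnorm(n * 3), n)
    y <- sample(1:5, n, TRUE)
  })
  em <- encoded_matrix(X, y, paste0("c", 1:5))
  stub <- learner_spec("memorize")
  in_sample <- fit_learner(stub, X, y, 5)
  expect_equal(unname(predict(in_sample, X)), y) # would leak if allowed
  meta <- build_meta_features(em, stack_config(m = 2, k = 5,
                                               base_spec = stub))
  oof_acc <- mean(meta$Z[, 1] == y)
  expect_lt(oof_acc, 0.35) # chance is 0.2; perfect leak would be 1.0
})

test_that("meta-features are bit-identical across runs with one seed", {
  em <- make_blobs(40, C = 2, sep = 3, seed = 6)
  cfg <- stack_config(m = 2, k = 3, master_seed = 11)
  m1 <- build_meta_features(em, cfg)
  m2 <- build_meta_features(em, cfg)
  expect_identical(m1$Z, m2$Z)
  expect_identical(m1$fold_assignment, m2$fold_assignment)
})

test_that("fold complements missing a class trigger a warning", {
  X <- matrix(rnorm(20), 10)
  y <- c(rep(1L, 9), 2L)
  em <- encoded_matrix(X, y, c("a", "b"))
  cfg <- stack_config(m = 1, k = 5, meta_mode = "proba", master_seed = 2)
  expect_warning(build_meta_features(em, cfg), "missing")
})

test_that("the self-stack classifies well-separated Gaussians", {
  em <- make_blobs(100, C = 2, sep = 4, seed = 12) # n = 400
  accs <- vapply(0:4, function(s) {
    sp <- split_train_test(em, 0.2, seed = s)
    ss <- fit_self_stack(sp$train, stack_config(master_seed = s))
    mean(predict(ss, sp$test$X) == sp$test$y)
  }, numeric(1))
  expect_true(all(accs >= 0.95))
})

test_that("a single-base stack with a passthrough meta-learner reduces to its base", {
  em <- make_blobs(60, C = 3, sep = 3, seed = 13)
  cfg <- stack_config(m = 1, k = 3, meta_spec = learner_spec("argmax"),
                      master_seed = 4)
  ss <- fit_self_stack(em, cfg)
  expect_equal(predict(ss, em$X), unname(predict(ss$base_models[[1]], em$X)))
})

test_that("degenerate stack inputs error cleanly", {
  em1 <- encoded_matrix(matrix(rnorm(20), 10), rep(1L, 10), "a")
  expect_error(fit_self_stack(em1), "single class")
  em <- make_blobs(30, C = 2, sep = 3, seed = 14)
  ss <- fit_self_stack(em, stack_config(m = 2, k = 3))
  expect_equal(predict(ss, em$X[0, , drop = FALSE]), integer(0))
  expect_error(predict(ss, em$X[, 1, drop = FALSE]), "mismatch")
})

test_that("stack predictions are deterministic given the master seed", {
  em <- make_blobs(50, C = 2, sep = 2, seed = 15)
  s1 <- fit_self_stack(em, stack_config(master_seed = 21))
  s2 <- fit_self_stack(em, stack_config(master_seed = 21))
  expect_identical(predict(s1, em$X), predict(s2, em$X))
})
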