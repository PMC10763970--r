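test_that("confusion matrices tally true/predicted pairs", {
  cm <- confusion_matrix(c(1, 2, 3), c(1, 2, 3), c("a", "b", "c"))
  expect_equal(unname(diag(cm$counts)), c(1L, 1L, 1L))
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0L)
  cm2 <- confusion_matrix(c(1, 1, 2, 2), c(1, 1, 2, 1), c("a", "b"))
  expect_equal(sum(diag(cm2$counts)), 3L)
  expect_error(confusion_matrix(1:3, 1:2, c("a", "b", "c")), "differ")
  withr::with_seed(21, {
    for (r in 1:10) {
      y_true <- sample(1:4, 50, TRUE)
      y_pred <- sample(1:4, 50, TRUE)
      cm <- confusion_matrix(y_true, y_pred, paste0("c", 1:4))
      expect_equal(unname(cm$counts), brute_confusion(y_true, y_pred, 4))
    }
  })
})

test_that("per-class metrics follow the one-vs-rest formulas", {
  # harmonic mean of equals is the value itself
  cm <- confusion_matrix(c(1, 1, 2, 2), c(1, 2, 1, 2), c("a", "b"))
  pc <- per_class_metrics(cm)
  expect_equal(pc$precision, pc$f1)
  # zero-denominator convention: a class never present nor predicted as
  # itself scores 0 across the board
  cm0 <- confusion_matrix(c(1, 1, 2), c(1, 1, 1), c("a", "b"))
  pc0 <- per_class_metrics(cm0)
  expect_equal(pc0$precision[2], 0)
  expect_equal(pc0$recall[2], 0)
  expect_equal(pc0$f1[2], 0)
  # f1 lies between precision and recall
  withr::with_seed(22, {
    for (r in 1:20) {
      cm <- confusion_matrix(sample(1:3, 40, TRUE), sample(1:3, 40, TRUE),
                             paste0("c", 1:3))
      pc <- per_class_metrics(cm)
      expect_true(all(pc$f1 >= pmin(pc$precision, pc$recall) - 1e-12))
      expect_true(all(pc$f1 <= pmax(pc$precision, pc$recall) + 1e-12))
    }
  })
})

test_that("printed-table worked examples reproduce at two decimals", {
  # per-class F1 from precision 0.98 and recall 1.00
  expect_equal(round_half_up(f1_score(0.98, 1.00), 2), 0.99)
  # macro precision over five per-class values rounding up to 1.00
  pc <- data.frame(precision = c(1, 1, 1, 1, 0.98),
                   recall = c(1, 1, 1, 1, 1),
                   f1 = c(1, 1, 1, 1, 0.99))
  mac <- macro_average(pc)
  expect_equal(unname(mac["macro_precision"]), 0.996)
  expect_equal(round_half_up(mac["macro_precision"], 2), 1.00,
               ignore_attr = TRUE)
})

test_that("macro averaging is the unweighted mean and rejects empties", {
  pc <- data.frame(precision = c(0.5, 0.7), recall = c(0.4, 0.8),
                   f1 = c(0.44, 0.74))
  expect_equal(unname(macro_average(pc)), c(0.6, 0.6, 0.59))
  expect_error(macro_average(pc[0, ]), "no classes")
})

test_that("accuracy is trace over total and matches its complement oracle", {
  cm <- confusion_matrix(1:3, 1:3, c("a", "b", "c"))
  expect_equal(accuracy(cm), 1)
  cm2 <- confusion_matrix(c(1, 1, 2, 2), c(1, 1, 2, 1), c("a", "b"))
  expect_equal(accuracy(cm2), 0.75)
  withr::with_seed(23, {
    for (r in 1:10) {
      cm <- confusion_matrix(sample(1:3, 30, TRUE), sample(1:3, 30, TRUE),
                             paste0("c", 1:3))
      off <- sum(cm$counts) - sum(diag(cm$counts))
      expect_equal(accuracy(cm), 1 - off / sum(cm$counts))
    }
  })
})

test_that("metrics agree with the brute-force implementation to 1e-12", {
  withr::with_seed(24, {
    for (r in 1:200) {
      C <- sample(2:5, 1)
      n <- sample(5:60, 1)
      y_true <- sample(seq_len(C), n, TRUE)
      y_pred <- sample(seq_len(C), n, TRUE)
      rep <- metric_report(y_true, y_pred, paste0("c", seq_len(C)))
      want <- brute_metrics(y_true, y_pred, C)
      expect_equal(rep$accuracy, want$accuracy, tolerance = 1e-12)
      expect_equal(rep$per_class$precision, want$precision,
                   tolerance = 1e-12)
      expect_equal(rep$per_class$recall, want$recall, tolerance = 1e-12)
      expect_equal(rep$per_class$f1, want$f1, tolerance = 1e-12)
      expect_equal(rep$macro_f1, want$macro_f1, tolerance = 1e-12)
    }
  })
})

test_that("macro F1 exposes minority failure that accuracy masks", {
  y_true <- c(rep(1L, 95), rep(2L, 5))
  y_pred <- rep(1L, 100) # minority class always missed
  rep <- metric_report(y_true, y_pred, c("maj", "min"))
  expect_equal(rep$accuracy, 0.95)
  expect_lt(rep$macro_f1, rep$accuracy)
})

test_that("report rounding is half away from zero", {
  expect_equal(round_half_up(0.995, 2), 1.00)
  expect_equal(round_half_up(0.985, 2), 0.99)
  expect_equal(round_half_up(0.994, 2), 0.99)
  expect_equal(round_half_up(0.9951, 3), 0.995)
  expect_equal(round_half_up(-0.995, 2), -1.00)
})

test_that("cross-validation partitions and summaries are well-formed", {
  em <- make_blobs(25, C = 2, sep = 3, seed = 31) # n = 50
  cv <- kfold_cv(learner_spec("constant", list(value = 1)), em, k = 10,
                 seed = 2)
  folds <- cv$fold_assignment
  sizes <- tabulate(folds, 10)
  expect_equal(sum(sizes), 50)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  expect_equal(cv$sd, stats::sd(cv$fold_accuracies))
  cv2 <- kfold_cv(learner_spec("constant", list(value = 1)), em, k = 10,
                  seed = 2)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_error(kfold_cv(learner_spec("constant"), em, k = 51), "exceeds")
})

test_that("leave-one-out on n = 10 yields 10 singleton folds", {
  em <- encoded_matrix(matrix(rnorm(20), 10), rep(1:2, 5), c("a", "b"))
  cv <- kfold_cv(learner_spec("constant", list(value = 1)), em, k = 10,
                 seed = 1)
  expect_equal(tabulate(cv$fold_assignment, 10), rep(1L, 10))
  expect_length(cv$fold_accuracies, 10)
})

test_that("a constant classifier's CV accuracy is the majority proportion", {
  # 100 rows in 10 equal folds: the mean of per-fold proportions equals the
  # overall class-1 proportion exactly
  em <- encoded_matrix(matrix(rnorm(200), 100), rep(1:5, each = 20),
                       paste0("c", 1:5))
  cv <- kfold_cv(learner_spec("constant", list(value = 1)), em, k = 10,
                 seed = 3)
  expect_equal(cv$mean_accuracy, 0.2)
})

test_that("the paired t-test follows the closed form and its conventions", {
  # eight paired scores give df = 7
  a <- c(0.99, 1.00, 1.00, 1.00, 0.98, 0.95, 0.95, 0.95)
  b <- c(0.97, 0.98, 0.97, 0.97, 0.98, 0.97, 0.94, 0.95)
  tt <- paired_ttest(a, b)
  expect_equal(tt$df, 7L)
  ht <- stats::t.test(a, b, paired = TRUE)
  expect_equal(tt$t_statistic, unname(ht$statistic))
  expect_equal(tt$p_value, ht$p.value)
  # identical scores: t = 0, never rejects
  t0 <- paired_ttest(a, a)
  expect_equal(t0$t_statistic, 0)
  expect_false(t0$reject_null)
  # hand case d = (1, 2, 3): t = mean/sd * sqrt(3) = 2 / 1 * sqrt(3)
  th <- paired_ttest(c(1, 2, 3), c(0, 0, 0))
  expect_equal(th$t_statistic, 2 * sqrt(3))
  expect_equal(th$p_value, 2 * stats::pt(-2 * sqrt(3), 2))
  # zero-variance non-zero differences: infinite t, p = 0
  ti <- paired_ttest(c(1, 1, 1), c(0, 0, 0))
  expect_equal(ti$t_statistic, Inf)
  expect_equal(ti$p_value, 0)
  expect_true(ti$reject_null)
  expect_error(paired_ttest(1:3, 1:4), "equal length")
})

test_that("the unpaired alternative matches Welch's test", {
  withr::with_seed(25, {
    a <- rnorm(8, 0.9, 0.05)
    b <- rnorm(8, 0.8, 0.05)
  })
  tt <- unpaired_ttest(a, b)
  ht <- stats::t.test(a, b)
  expect_equal(tt$t_statistic, unname(ht$statistic))
  expect_equal(tt$p_value, ht$p.value)
})
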