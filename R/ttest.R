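#' Paired t-test between two models' evaluation scores
#'
#' Two-sided paired t-test on the differences `d = scores_a - scores_b`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom. The
#' conventional comparison pairs each model's eight evaluation scores
#' (accuracy and the three macro metrics, under the original and the
#' down-sampled setting), giving df = 7.
#'
#' Degenerate cases are reported rather than erroring: identical score
#' vectors give `t = 0`, `p = 1`; zero-variance differences with a non-zero
#' mean give an infinite `t` with `p = 0`.
#'
#' @param scores_a,scores_b numeric vectors of equal length (>= 2), paired
#'   by position.
#' @param alpha significance level (default 0.05).
#' @return An object of class `ttest_result`: `t_statistic`, `df`,
#'   `p_value`, `alpha`, `reject_null`, `mean_difference`.
#' @export
paired_ttest <- function(scores_a, scores_b, alpha = 0.05) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length", call. = FALSE)
  n <- length(scores_a)
  if (n < 2) stop("need at least 2 paired observations", call. = FALSE)
  d <- scores_a - scores_b
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t_stat <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(list(t_statistic = t_stat, df = n - 1L, p_value = p,
                 alpha = alpha, reject_null = p < alpha,
                 mean_difference = md, n = n),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<ttest_result> t = %.3f, df = %d, p = %.4g (%s H0 at alpha = %g)\n",
              x$t_statistic, x$df, x$p_value,
              if (x$reject_null) "reject" else "retain", x$alpha))
  invisible(x)
}

#' Welch two-sample t-test (unpaired alternative)
#'
#' Provided as the unpaired alternative to [paired_ttest()] for score
#' vectors that are not naturally paired; a thin wrapper over
#' [stats::t.test()].
#'
#' @inheritParams paired_ttest
#' @return A `ttest_result`.
#' @export
unpaired_ttest <- function(scores_a, scores_b, alpha = 0.05) {
  ht <- stats::t.test(scores_a, scores_b, paired = FALSE)
  structure(list(t_statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 alpha = alpha, reject_null = ht$p.value < alpha,
                 mean_difference = mean(scores_a) - mean(scores_b),
                 n = length(scores_a)),
            class = "ttest_result")
}
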