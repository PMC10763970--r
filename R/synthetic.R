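#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical shape of the thyroid screening
#' panel: a heavily skewed multi-class label distribution (defaults match
#' the panel's five modelling classes, from 233 primary-hypothyroid up to
#' 6771 no-condition records), a handful of strictly positive hormone-like
#' continuous measurements, t/f flag-like binary features, and '?'-style
#' missingness in the continuous columns.
#'
#' Class separation is controlled entirely by `effect_size` and
#' `flip_rate`: each class carries a distinct bit pattern; continuous
#' feature `h` for a class with bit 1 is shifted by `effect_size` standard
#' deviations on the log scale, and binary feature `h` has success
#' probability `0.5 + flip_rate * (bit - 0.5)`. At
#' `effect_size = flip_rate = 0` the labels are independent of every
#' feature.
#'
#' @param class_counts named integer vector mapping class code to record
#'   count.
#' @param n_continuous number of continuous features (default 6; the first
#'   six are named like the hormone panel).
#' @param n_binary number of binary flag features (default 15).
#' @param effect_size per-class mean shift, in SD units on the log scale
#'   (default 1: overlapping classes).
#' @param flip_rate per-class Bernoulli skew of the binary features, in
#'   `[0, 1]` (default 0.3).
#' @param missing_rate fraction of continuous entries replaced by the
#'   missing token (default 0.03).
#' @param seed integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(class_counts = c("-" = 6771L, "K" = 436L,
                                              "G" = 359L, "I" = 346L,
                                              "F" = 233L),
                             n_continuous = 6L, n_binary = 15L,
                             effect_size = 1, flip_rate = 0.3,
                             missing_rate = 0.03, seed = 1L) {
  stopifnot(length(class_counts) >= 1, all(class_counts >= 1),
            !is.null(names(class_counts)),
            n_continuous >= 1, n_binary >= 0,
            effect_size >= 0, flip_rate >= 0, flip_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  for (code in names(class_counts)) parse_diagnosis(code)
  structure(list(class_counts = class_counts,
                 n_continuous = as.integer(n_continuous),
                 n_binary = as.integer(n_binary),
                 effect_size = effect_size, flip_rate = flip_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "generator_config")
}

# distinct per-class direction patterns: bit h (cycled) of the class index
class_bit <- function(class_index, feature_index, n_classes) {
  nbits <- max(1L, ceiling(log2(n_classes)))
  bit <- (feature_index - 1L) %% nbits
  bitwAnd(bitwShiftR(class_index, bit), 1L)
}

synthetic_schema <- function(n_continuous, n_binary) {
  cont <- c("age", "TSH", "T3", "TT4", "T4U", "FTI")
  cont_names <- if (n_continuous <= 6L) cont[seq_len(n_continuous)] else
    c(cont, paste0("cont_", seq_len(n_continuous - 6L)))
  bin_names <- if (n_binary) paste0("flag_", seq_len(n_binary)) else
    character(0)
  feature_schema(c(cont_names, bin_names, "target", "patient_id"),
                 c(rep("continuous", n_continuous),
                   rep("binary", n_binary), "target", "identifier"))
}

#' Generate a synthetic imbalanced cohort
#'
#' Draws, per class, continuous features from class-shifted log-normal
#' distributions and binary features from class-skewed Bernoullis, inserts
#' '?' missing tokens into continuous columns at `missing_rate`, interleaves
#' the class blocks in a deterministic seeded order, and returns a raw
#' [cohort()] carrying a schema in the reader's dialect — so the full
#' read/encode/balance/split/model pipeline can run end-to-end on it.
#'
#' @param config a [generator_config()].
#' @return A [cohort()].
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  counts <- config$class_counts
  Cn <- length(counts)
  schema <- synthetic_schema(config$n_continuous, config$n_binary)
  withr::with_seed(config$seed, {
    blocks <- lapply(seq_len(Cn), function(ci) {
      nc <- counts[[ci]]
      cont <- sapply(seq_len(config$n_continuous), function(h) {
        mu <- config$effect_size * class_bit(ci - 1L, h, Cn)
        v <- sprintf("%.4f", exp(stats::rnorm(nc, mean = mu, sd = 1)))
        miss <- stats::runif(nc) < config$missing_rate
        v[miss] <- schema$missing_token
        v
      })
      cont <- matrix(cont, nrow = nc)
      bin <- if (config$n_binary) {
        matrix(sapply(seq_len(config$n_binary), function(h) {
          p <- 0.5 + config$flip_rate *
            (class_bit(ci - 1L, h, Cn) - 0.5)
          c("f", "t")[stats::rbinom(nc, 1, p) + 1L]
        }), nrow = nc)
      } else matrix(character(0), nc, 0)
      cbind(cont, bin, rep(names(counts)[ci], nc))
    })
    m <- do.call(rbind, blocks)
    m <- cbind(m, sprintf("P%06d", seq_len(nrow(m))))
    perm <- sample.int(nrow(m))
    m <- m[perm, , drop = FALSE]
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- schema$columns$name
    cohort(df, schema)
  },
  .rng_kind = "Mersenne-Twister", .rng_sample_kind = "Rejection")
}

#' Generate a balanced, widely separated cohort
#'
#' Convenience preset for sanity-checking classifiers: `n_classes` classes
#' of `n_per_class` records each, with large class separation
#' (`effect_size = 4`, `flip_rate = 0.6`) and no missingness, so a
#' well-configured classifier should reach near-perfect held-out accuracy.
#'
#' @param n_per_class records per class (default 230).
#' @param n_classes number of classes (default 5).
#' @param seed integer seed.
#' @return A [cohort()].
#' @export
make_separable_cohort <- function(n_per_class = 230L, n_classes = 5L,
                                  seed = 1L) {
  stopifnot(n_per_class >= 20, n_classes >= 2, n_classes <= 21)
  codes <- c("-", "F", "G", "I", "K",
             setdiff(names(diagnosis_codes()), c("-", "F", "G", "I", "K")))
  counts <- stats::setNames(rep(as.integer(n_per_class), n_classes),
                            codes[seq_len(n_classes)])
  generate_cohort(generator_config(class_counts = counts,
                                   effect_size = 4, flip_rate = 0.6,
                                   missing_rate = 0, seed = seed))
}
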