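# Independent brute-force oracles and small fixture builders. Oracles are
# written as plain loops so they share no code with the implementation.

# pairwise tally oracle for the confusion matrix
brute_confusion <- function(y_true, y_pred, C) {
  m <- matrix(0L, C, C)
  for (i in seq_along(y_true))
    for (a in 1:C) for (b in 1:C)
      if (y_true[i] == a && y_pred[i] == b) m[a, b] <- m[a, b] + 1L
  m
}

# one-vs-rest metrics computed from scratch per class
brute_metrics <- function(y_true, y_pred, C) {
  prec <- rec <- f1 <- numeric(C)
  for (c in 1:C) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec[c] + rec[c] > 0)
      2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
  }
  list(precision = prec, recall = rec, f1 = f1,
       accuracy = sum(y_true == y_pred) / length(y_true),
       macro_precision = sum(prec) / C,
       macro_recall = sum(rec) / C,
       macro_f1 = sum(f1) / C)
}

# exhaustive count-and-argmax mode with lowest-index tie-break
brute_mode <- function(labels, C) {
  counts <- integer(C)
  for (l in labels) counts[l] <- counts[l] + 1L
  best <- 1L
  for (c in 2:C) if (counts[c] > counts[best]) best <- c
  best
}

# two (or more) well-separated Gaussian classes as an encoded_matrix
make_blobs <- function(n_per_class = 200, C = 2, sep = 4, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(C), function(c) {
      cbind(rnorm(n_per_class, sep * c), rnorm(n_per_class, -sep * c))
    }))
    y <- rep(seq_len(C), each = n_per_class)
    ord <- sample.int(length(y))
    encoded_matrix(X[ord, ], y[ord], paste0("c", seq_len(C)))
  })
}

# a tiny raw cohort with explicit values, for encoding tests
toy_cohort <- function(values, kinds = NULL, labels = NULL) {
  n <- length(values[[1]])
  if (is.null(labels)) labels <- rep(c("F", "-"), length.out = n)
  if (is.null(kinds)) kinds <- rep("continuous", length(values))
  df <- as.data.frame(lapply(values, as.character),
                      stringsAsFactors = FALSE)
  df$target <- labels
  df$id <- sprintf("r%d", seq_len(n))
  sch <- feature_schema(c(names(values), "target", "id"),
                        c(kinds, "target", "identifier"))
  cohort(df, sch)
}

# raw headerless thyroid0387-style lines for the given diagnosis fields
raw_thyroid_lines <- function(diagnoses) {
  sch <- thyroid_schema()
  vapply(seq_along(diagnoses), function(i) {
    vals <- character(0)
    for (j in seq_len(nrow(sch$columns) - 2L)) {
      kind <- sch$columns$kind[j]
      nm <- sch$columns$name[j]
      vals <- c(vals, switch(kind,
                             continuous = sprintf("%.1f", 1 + i + j / 10),
                             binary = if (nm == "sex") "F" else "f",
                             categorical = "SVI"))
    }
    paste(c(vals, diagnoses[i]), collapse = ",")
  }, "")
}
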