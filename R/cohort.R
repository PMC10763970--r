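#' Construct a cohort of patient records
#'
#' A cohort is a raw (character-valued) rectangular table of patient records
#' tied to a [feature_schema()]. Missing values keep the schema's missing
#' token; the target column holds diagnosis code strings (possibly compound).
#'
#' @param data data.frame of character columns, names and order matching the
#'   schema.
#' @param schema a [feature_schema()].
#' @return An object of class `cohort`.
#' @export
cohort <- function(data, schema) {
  stopifnot(inherits(schema, "feature_schema"), is.data.frame(data))
  if (!identical(names(data), schema$columns$name))
    stop("cohort columns do not match the schema", call. = FALSE)
  data[] <- lapply(data, as.character)
  tcol <- schema$columns$name[schema$columns$kind == "target"]
  for (v in data[[tcol]]) parse_diagnosis(v)  # closed-set validation
  rownames(data) <- NULL
  structure(list(schema = schema, data = data), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<cohort> %d records x %d columns; %d class(es)\n",
              nrow(x$data), ncol(x$data), length(cc)))
  if (length(cc))
    print(utils::head(cc, 10))
  invisible(x)
}

#' Number of records in a cohort
#' @param x a `cohort`.
#' @return Integer record count.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "cohort"))
  nrow(x$data)
}

target_column <- function(schema) {
  schema$columns$name[schema$columns$kind == "target"]
}

#' Diagnosis label of every record
#'
#' Returns the target field of each record with any record-id suffix stripped,
#' i.e. the (possibly compound) diagnosis code string.
#'
#' @param x a `cohort`.
#' @return Character vector of length `n_records(x)`.
#' @export
cohort_labels <- function(x) {
  stopifnot(inherits(x, "cohort"))
  raw <- x$data[[target_column(x$schema)]]
  vapply(raw, function(v) paste(parse_diagnosis(v), collapse = ""), "",
         USE.NAMES = FALSE)
}

#' Read a thyroid-style patient table
#'
#' Two dialects are accepted. The raw UCI thyroid0387 dialect has no header
#' and one fewer physical field than the schema: the last field combines the
#' diagnosis codes and the record id as `"codes[record_id]"`, which is split
#' into the target and identifier columns. Alternatively, a plain CSV whose
#' header matches the schema column names is read directly. Missing values
#' (the schema's missing token) are preserved untouched; every diagnosis
#' field is validated against the closed code set.
#'
#' @param path path to the file.
#' @param schema a [feature_schema()]; defaults to [thyroid_schema()].
#' @return A [cohort()].
#' @export
read_thyroid_table <- function(path, schema = thyroid_schema()) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no records in ", path, call. = FALSE)
  nm <- schema$columns$name
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  if (identical(trimws(header), nm)) {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE)
    return(cohort(df, schema))
  }
  # headerless raw dialect: diagnosis and patient id share the last field
  fields <- strsplit(lines, ",", fixed = TRUE)
  want <- length(nm) - 1L
  nf <- lengths(fields)
  if (any(nf != want)) {
    bad <- which(nf != want)[1]
    stop(sprintf("line %d has %d fields, expected %d", bad, nf[bad], want),
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  diag_raw <- m[, want]
  codes <- vapply(diag_raw, function(v) paste(parse_diagnosis(v),
                                              collapse = ""), "",
                  USE.NAMES = FALSE)
  ids <- sub("^[^\\[|]*[\\[|]?", "", diag_raw)
  ids <- sub("\\]$", "", ids)
  ids[!nzchar(ids)] <- NA_character_
  kinds <- schema$columns$kind
  if (!identical(utils::tail(kinds, 2), c("target", "identifier")))
    stop("the headerless dialect requires a schema ending in ",
         "(target, identifier) columns", call. = FALSE)
  df <- as.data.frame(m[, -want, drop = FALSE], stringsAsFactors = FALSE)
  df[[want]] <- codes
  df[[want + 1L]] <- ids
  names(df) <- nm
  cohort(df, schema)
}

#' Write a cohort as a normalized CSV
#'
#' Writes the cohort with an explicit header matching its schema; the file can
#' be read back with [read_thyroid_table()] and the same schema.
#'
#' @param x a `cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(x$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only single-label records
#'
#' Records whose diagnosis decomposes into more than one code are excluded
#' from modelling cohorts (the task is single-label multi-class); exclusions
#' are reported via a message, never silent.
#'
#' @param x a `cohort`.
#' @return A `cohort` of single-label records, with attribute
#'   `"excluded_multilabel"` giving the number of dropped records.
#' @export
filter_single_label <- function(x) {
  stopifnot(inherits(x, "cohort"))
  lab <- cohort_labels(x)
  multi <- nchar(lab) > 1L
  if (any(multi))
    message(sum(multi), " multi-label record(s) excluded from the cohort")
  out <- cohort(x$data[!multi, , drop = FALSE], x$schema)
  attr(out, "excluded_multilabel") <- sum(multi)
  out
}

#' Per-class record counts
#'
#' Tallies records by diagnosis label, in descending count order (ties broken
#' by code for determinism).
#'
#' @param x a `cohort`.
#' @return Named integer vector of counts summing to `n_records(x)`.
#' @export
class_counts <- function(x) {
  stopifnot(inherits(x, "cohort"))
  lab <- cohort_labels(x)
  if (!length(lab)) return(structure(integer(0), names = character(0)))
  tab <- table(lab)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  ord <- order(-counts, sort_key(names(counts)), method = "radix")
  counts[ord]
}

# locale-independent ordering key for class codes
sort_key <- function(x) {
  vapply(x, function(s) paste(sprintf("%03d", utf8ToInt(s)), collapse = ""),
         "", USE.NAMES = FALSE)
}
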