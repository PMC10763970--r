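#' Feature schema for a tabular patient cohort
#'
#' A schema is an ordered list of columns, each tagged with a kind that drives
#' parsing, encoding and modelling: `binary` (t/f-style flags), `continuous`
#' (numeric lab measurements), `categorical` (unordered codes), `identifier`
#' (record ids, never used as model features) and `target` (the diagnosis
#' column). Exactly one column must be the target.
#'
#' @param names character vector of unique column names, in file order.
#' @param kinds character vector, same length, each one of
#'   `"binary"`, `"continuous"`, `"categorical"`, `"identifier"`, `"target"`.
#' @param missing_token token representing a missing value in raw files
#'   (default `"?"`).
#' @return An object of class `feature_schema`.
#' @seealso [thyroid_schema()] for the 31-column thyroid panel layout.
#' @export
feature_schema <- function(names, kinds, missing_token = "?") {
  stopifnot(is.character(names), is.character(kinds),
            length(names) == length(kinds))
  kinds <- match.arg(kinds,
                     c("binary", "continuous", "categorical", "identifier",
                       "target"),
                     several.ok = TRUE)
  if (anyDuplicated(names))
    stop("schema column names must be unique", call. = FALSE)
  if (sum(kinds == "target") != 1L)
    stop("schema must contain exactly one target column", call. = FALSE)
  structure(
    list(columns = data.frame(name = names, kind = kinds,
                              stringsAsFactors = FALSE),
         missing_token = missing_token),
    class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  tab <- table(x$columns$kind)
  cat(sprintf("<feature_schema> %d columns (%s); missing token '%s'\n",
              nrow(x$columns),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$missing_token))
  invisible(x)
}

#' Schema of the UCI thyroid0387-style panel
#'
#' The 31-column layout of the thyroid screening panel: patient age and sex,
#' fifteen binary history/medication flags, five serum hormone measurements
#' (TSH, T3, TT4, T4U, FTI) plus TBG, each paired with a binary
#' "was this assay run" indicator, the referral source, the diagnosis target
#' and a patient identifier.
#'
#' @return A [feature_schema()].
#' @export
thyroid_schema <- function() {
  hormones <- c("TSH", "T3", "TT4", "T4U", "FTI", "TBG")
  nm <- c("age", "sex", "on_thyroxine", "query_on_thyroxine",
          "on_antithyroid_meds", "sick", "pregnant", "thyroid_surgery",
          "I131_treatment", "query_hypothyroid", "query_hyperthyroid",
          "lithium", "goitre", "tumor", "hypopituitary", "psych",
          as.vector(rbind(paste0(hormones, "_measured"), hormones)),
          "referral_source", "target", "patient_id")
  kd <- c("continuous", "binary", rep("binary", 14),
          rep(c("binary", "continuous"), 6),
          "categorical", "target", "identifier")
  feature_schema(nm, kd)
}

#' The closed set of thyroid diagnosis codes
#'
#' Single-letter condition codes (A through T) plus `"-"` for a record with
#' no thyroid condition. Compound diagnoses are strings of several letters.
#'
#' @return Named character vector mapping code to description.
#' @export
diagnosis_codes <- function() {
  c("A" = "hyperthyroid",
    "B" = "T3 toxic",
    "C" = "toxic goitre",
    "D" = "secondary toxic",
    "E" = "hypothyroid",
    "F" = "primary hypothyroid",
    "G" = "compensated hypothyroid",
    "H" = "secondary hypothyroid",
    "I" = "increased binding protein",
    "J" = "decreased binding protein",
    "K" = "concurrent non-thyroidal illness",
    "L" = "consistent with replacement therapy",
    "M" = "under replaced",
    "N" = "over replaced",
    "O" = "antithyroid drugs",
    "P" = "I131 treatment",
    "Q" = "surgery",
    "R" = "discordant assay results",
    "S" = "elevated TBG",
    "T" = "elevated thyroid hormones",
    "-" = "no condition")
}

#' Infer a feature schema from a normalized CSV header
#'
#' For CSVs written by [write_cohort()]: if the header matches the thyroid
#' panel layout, [thyroid_schema()] is returned; otherwise column kinds are
#' inferred from the naming conventions of the synthetic generator
#' (`age`/hormone/`cont_*` columns are continuous, `flag_*` and `sex` binary,
#' `referral_source` categorical, `patient_id` the identifier, `target` the
#' target).
#'
#' @param path path to a CSV with a header row.
#' @return A [feature_schema()].
#' @export
infer_schema <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  thy <- thyroid_schema()
  if (identical(header, thy$columns$name)) return(thy)
  cont <- c("age", "TSH", "T3", "TT4", "T4U", "FTI", "TBG")
  kinds <- vapply(header, function(nm) {
    if (nm == "target") "target"
    else if (nm == "patient_id") "identifier"
    else if (nm == "referral_source") "categorical"
    else if (nm %in% cont || grepl("^cont_", nm)) "continuous"
    else "binary"
  }, "", USE.NAMES = FALSE)
  feature_schema(header, kinds)
}

#' Parse a raw diagnosis field into diagnosis codes
#'
#' The source dialect stores the diagnosis as `"codes[record_id]"` (or
#' `"codes|record_id"`); the suffix is stripped and the remaining string is
#' decomposed one code per character. `"-"` yields the single no-condition
#' code; a multi-letter string such as `"AK"` is a compound (multi-label)
#' diagnosis.
#'
#' @param raw raw diagnosis field, e.g. `"F"`, `"-"`, `"AK"` or
#'   `"F[840801013]"`.
#' @return Character vector of single-character codes.
#' @export
parse_diagnosis <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  code <- sub("[\\[|].*$", "", raw)
  code <- trimws(code)
  if (!nzchar(code))
    stop("empty diagnosis field: '", raw, "'", call. = FALSE)
  chars <- strsplit(code, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(diagnosis_codes()))
  if (length(bad))
    stop("unknown diagnosis code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  chars
}
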