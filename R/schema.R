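# Cohort data model: one row per nurse, closed demographic category sets,
# optional raw questionnaire items, scale scores and the raw hair-cortisol
# moderator (pg/mg).

#' Closed category sets and canonical column groups
#'
#' @description
#' `rosmod_departments()` and `rosmod_shifts()` return the closed sets of
#' demographic categories a cohort may use.  `jcq_item_names()` /
#' `mbi_item_names()` return the canonical raw-item column names:
#' JCQ items 1-6 skill discretion, 7-9 decision authority, 10-14
#' psychological demands, 15-18 supervisor support, 19-22 coworker support;
#' MBI items 1-5 emotional exhaustion, 6-10 depersonalization,
#' 11-16 professional efficiency.
#'
#' @return A character vector.
#' @export
rosmod_departments <- function() {
  c("ICU", "EICU", "emergency", "radiotherapy", "psychology",
    "rehabilitation", "other")
}

#' @rdname rosmod_departments
#' @export
rosmod_shifts <- function() c("three_shift_8h", "two_shift_12h")

#' @rdname rosmod_departments
#' @export
jcq_item_names <- function() sprintf("jcq_%02d", 1:22)

#' @rdname rosmod_departments
#' @export
mbi_item_names <- function() sprintf("mbi_%02d", 1:16)

scale_variables <- function() {
  c("job_control", "psych_demands", "supervisor_support", "coworker_support")
}

outcome_variables <- function() c("ee", "dp", "pe")

#' Construct and validate a cohort table
#'
#' A cohort table is a validated `data.frame` (class `cohort_table`) with one
#' row per subject.  Required columns: `subject_id` (unique), `department`
#' and `shift_pattern` (members of the closed sets), `tenure_years`
#' (non-negative), `hcc_raw` (cortisol pg/mg, strictly positive, never
#' missing).  Either raw item columns (`jcq_01`..`jcq_22`, `mbi_01`..
#' `mbi_16`) or scale-score columns (`job_control`, `psych_demands`,
#' `supervisor_support`, `coworker_support`, `ee`, `dp`, `pe`) must be
#' present; scale scores may contain `NA` (to be EM-imputed) but items, when
#' present, must lie in their declared ranges (1-4 JCQ, 1-7 MBI).
#'
#' @param records a data.frame of subject records.
#' @param provenance free-text source tag stored as an attribute.
#' @return A `cohort_table`.
#' @export
cohort_table <- function(records, provenance = "unspecified") {
  if (!is.data.frame(records)) {
    rosmod_abort("rosmod_invalid_input", "`records` must be a data.frame")
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  req <- c("subject_id", "department", "shift_pattern", "tenure_years",
           "hcc_raw")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    rosmod_abort("rosmod_unmapped_column",
                 paste0("required column(s) missing: ",
                        paste(missing_cols, collapse = ", ")))
  }
  has_jcq <- all(jcq_item_names() %in% names(records))
  has_mbi <- all(mbi_item_names() %in% names(records))
  has_scales <- all(c(scale_variables(), outcome_variables()) %in%
                      names(records))
  if (!has_scales && !(has_jcq && has_mbi)) {
    rosmod_abort("rosmod_unmapped_column",
                 "need either raw item columns or scale-score columns")
  }

  if (anyDuplicated(records$subject_id)) {
    rosmod_abort("rosmod_invalid_input", "subject_id values must be unique")
  }
  check_category(records$department, rosmod_departments(), "department")
  check_category(records$shift_pattern, rosmod_shifts(), "shift_pattern")
  records$department <- factor(records$department,
                               levels = rosmod_departments())
  records$shift_pattern <- factor(records$shift_pattern,
                                  levels = rosmod_shifts())

  if (anyNA(records$tenure_years) || any(records$tenure_years < 0)) {
    rosmod_abort("rosmod_out_of_range",
                 "tenure_years must be present and non-negative")
  }
  if (anyNA(records$hcc_raw)) {
    rosmod_abort("rosmod_missing_moderator",
                 "hcc_raw (the moderator) must not be missing")
  }
  if (any(records$hcc_raw <= 0)) {
    rosmod_abort("rosmod_out_of_range",
                 "hcc_raw must be > 0 (log-transform must be defined)")
  }
  if (has_jcq) check_items(records[jcq_item_names()], 1L, 4L, "JCQ")
  if (has_mbi) check_items(records[mbi_item_names()], 1L, 7L, "MBI")

  structure(records,
            class = c("cohort_table", "data.frame"),
            provenance = provenance)
}

check_category <- function(x, allowed, what) {
  bad <- which(is.na(x) | !(as.character(x) %in% allowed))
  if (length(bad)) {
    rosmod_abort(
      "rosmod_invalid_category",
      sprintf("invalid %s value '%s' at row %d (allowed: %s)",
              what, as.character(x[bad[1]]), bad[1],
              paste(allowed, collapse = ", ")),
      rows = bad
    )
  }
}

check_items <- function(items, lo, hi, what) {
  m <- as.matrix(items)
  bad <- which(!is.na(m) & (m < lo | m > hi | m != floor(m)), arr.ind = TRUE)
  if (nrow(bad)) {
    rosmod_abort(
      "rosmod_out_of_range",
      sprintf("%s item response %s at row %d outside %d..%d",
              what, format(m[bad[1, 1], bad[1, 2]]), bad[1, 1], lo, hi)
    )
  }
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> n = %d, provenance: %s\n",
              nrow(x), attr(x, "provenance")))
  NextMethod()
}

#' Read a cohort from a delimited text file
#'
#' The only ingest path is delimited text with an explicit header.  Empty
#' fields and the string `"NA"` are read as missing.  An optional column
#' mapping renames file columns to the schema names before validation;
#' out-of-range items and unknown categories are rejected, not coerced.
#'
#' @param path file path.
#' @param sep field delimiter; comma default, tab accepted.
#' @param mapping optional named character vector, `c(file_column =
#'   "schema_column")`.
#' @param provenance source tag; defaults to the file path.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, sep = ",", mapping = NULL, provenance = path) {
  if (!file.exists(path)) {
    rosmod_abort("rosmod_missing_file", paste0("file not found: ", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!is.null(mapping)) {
    hit <- names(df) %in% names(mapping)
    names(df)[hit] <- unname(mapping[names(df)[hit]])
  }
  cohort_table(df, provenance = provenance)
}

#' Write a cohort or result table to delimited text
#'
#' Numeric columns are rendered with 17 significant digits so that
#' re-reading reproduces values to full stored precision; a structured JSON
#' rendition is written alongside when `json = TRUE`.
#'
#' @param results a data.frame (e.g. a cohort table, step summary or probe
#'   table).
#' @param path destination `.csv` path.
#' @param json also write `<path>.json` with full-precision values.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(results, path, json = TRUE) {
  if (!is.data.frame(results)) {
    rosmod_abort("rosmod_invalid_input", "`results` must be a data.frame")
  }
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    rosmod_abort("rosmod_unwritable", paste0("destination not writable: ", dir))
  }
  out <- as.data.frame(results, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  paths <- path
  if (json) {
    jpath <- paste0(path, ".json")
    jsonlite::write_json(results, jpath, digits = NA, na = "null",
                         dataframe = "columns")
    paths <- c(paths, jpath)
  }
  invisible(paths)
}

#' Account for cohort flow from recruitment to the analysis set
#'
#' Each stage percentage is 100 * stage / recruited, rounded to two
#' decimals; the analyzed set is `hair_provided - excluded`.
#'
#' @param recruited,questionnaire_complete,hair_provided,excluded
#'   non-negative counts; must satisfy `recruited >= questionnaire_complete
#'   >= hair_provided >= excluded`.
#' @return A `cohort_flow` list with counts and `*_pct` percentages.
#' @export
#' @examples
#' cohort_flow(495, 452, 408, 67)$analyzed_pct  # 68.89
cohort_flow <- function(recruited, questionnaire_complete, hair_provided,
                        excluded) {
  counts <- c(recruited, questionnaire_complete, hair_provided, excluded)
  if (!all(vapply(counts, is_count, logical(1)))) {
    rosmod_abort("rosmod_invalid_input", "counts must be non-negative integers")
  }
  analyzed <- hair_provided - excluded
  if (!(recruited >= questionnaire_complete &&
        questionnaire_complete >= hair_provided &&
        hair_provided >= excluded)) {
    rosmod_abort("rosmod_flow_monotonicity",
                 "counts must be monotone: recruited >= questionnaire >= hair >= excluded")
  }
  pct <- function(x) round2(100 * x / recruited, 2)
  structure(list(
    recruited = recruited,
    questionnaire_complete = questionnaire_complete,
    hair_provided = hair_provided,
    excluded = excluded,
    analyzed = analyzed,
    questionnaire_pct = pct(questionnaire_complete),
    hair_pct = pct(hair_provided),
    excluded_pct = pct(excluded),
    analyzed_pct = pct(analyzed)
  ), class = "cohort_flow")
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat(sprintf(
    "recruited %d -> questionnaire %d (%.2f%%) -> hair %d (%.2f%%) -> analyzed %d (%.2f%%)\n",
    x$recruited, x$questionnaire_complete, x$questionnaire_pct,
    x$hair_provided, x$hair_pct, x$analyzed, x$analyzed_pct))
  invisible(x)
}
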