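# Canonical questionnaire schema ---------------------------------------------

#' Canonical questionnaire fields
#'
#' The column names of the canonical CSV schema, in order: `year`, `ward`,
#' demographics (`age`, `gender`, `residence`, `education`), the surgery
#' indicator `q1_surgery`, the two tracked Likert items (`q2_postop_care`,
#' `q3_overall`) and the clinical algorithm inputs (`infection`,
#' `complication`, `protocol`, `innovation`, `pain`).
#'
#' @return Character vector of the 14 canonical field names.
#' @export
survey_fields <- function() {
  c("year", "ward", "age", "gender", "residence", "education",
    "q1_surgery", "q2_postop_care", "q3_overall",
    "infection", "complication", "protocol", "innovation", "pain")
}

#' Default fields counted by the missingness rule
#'
#' All canonical fields except the administrative `year` and `ward`.
#'
#' @return Character vector of 12 field names.
#' @export
missingness_fields <- function() setdiff(survey_fields(), c("year", "ward"))

#' Fields only applicable to operated respondents
#'
#' The postoperative-care rating and the clinical algorithm inputs are only
#' meaningful when `q1_surgery = "yes"`; for non-operated respondents they are
#' structurally blank, not non-response.
#'
#' @return Character vector of 6 field names.
#' @export
surgical_fields <- function() {
  c("q2_postop_care", "infection", "complication", "protocol",
    "innovation", "pain")
}

categorical_levels <- function() {
  list(gender = c("male", "female"),
       residence = c("urban", "rural"),
       education = c("primary", "secondary", "high_school", "university"),
       q1_surgery = c("yes", "no"),
       infection = c("yes", "no"),
       complication = c("yes", "no"),
       protocol = c("standard", "personalized"),
       innovation = c("yes", "no"))
}

#' Construct a survey dataset
#'
#' Validates and normalises a data frame of questionnaire records against the
#' canonical schema. `year` and `ward` are mandatory; absent optional columns
#' are added as all-missing. Range invariants (Likert in 1-5, pain in 0-10,
#' age in 0-120) and unknown categorical levels are enforced by setting the
#' offending cells to missing, with one warning carrying the cell count.
#'
#' @param records a data frame with at least `year` and `ward` columns.
#' @param provenance free-text source label attached to the dataset.
#' @return An object of class `survey_dataset` (a data frame in canonical
#'   column order).
#' @export
survey_dataset <- function(records, provenance = "in-memory") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  names(records) <- tolower(names(records))
  mandatory <- c("year", "ward")
  absent <- setdiff(mandatory, names(records))
  if (length(absent)) {
    abort(paste0("missing mandatory column(s): ",
                 paste(absent, collapse = ", ")), "postopsat_schema_error")
  }
  for (f in setdiff(survey_fields(), names(records))) {
    records[[f]] <- rep(NA, nrow(records))
  }
  d <- records[, survey_fields(), drop = FALSE]

  bad <- 0L
  to_int <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    suppressWarnings(as.numeric(as.character(x)))
  }
  for (f in c("year", "age", "q2_postop_care", "q3_overall", "pain")) {
    raw <- d[[f]]
    parsed <- to_int(raw)
    bad <- bad + sum(!is.na(raw) & raw != "" & is.na(parsed))
    d[[f]] <- parsed
  }
  rng <- list(q2_postop_care = c(1, 5), q3_overall = c(1, 5),
              pain = c(0, 10), age = c(0, 120))
  for (f in names(rng)) {
    out_of_range <- !is.na(d[[f]]) &
      (d[[f]] < rng[[f]][1] | d[[f]] > rng[[f]][2])
    bad <- bad + sum(out_of_range)
    d[[f]][out_of_range] <- NA
  }
  lik_nonint <- c("q2_postop_care", "q3_overall", "pain")
  for (f in lik_nonint) {
    nonint <- !is.na(d[[f]]) & d[[f]] != round(d[[f]])
    bad <- bad + sum(nonint)
    d[[f]][nonint] <- NA
  }
  lv <- categorical_levels()
  for (f in names(lv)) {
    x <- tolower(trimws(as.character(d[[f]])))
    x[x %in% c("", "na", "no answer")] <- NA
    unknown <- !is.na(x) & !x %in% lv[[f]]
    bad <- bad + sum(unknown)
    x[unknown] <- NA
    d[[f]] <- x
  }
  d$ward <- as.character(d$ward)
  if (bad > 0L) {
    warn(sprintf("%d cell(s) unparseable or out of range; set to missing", bad),
         "postopsat_parse_warning")
  }
  rownames(d) <- NULL
  structure(d, provenance = provenance, n_parse_issues = bad,
            class = c("survey_dataset", "data.frame"))
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("Survey dataset: %d record(s)  [%s]\n", nrow(x),
              attr(x, "provenance") %||% "unknown"))
  if (nrow(x)) {
    yrs <- sort(unique(x$year))
    cat("  years:", paste(yrs, collapse = ", "), "\n")
    cat("  wards:", length(unique(x$ward)), "\n")
  }
  invisible(x)
}

# Reading and writing ---------------------------------------------------------

#' Read a questionnaire CSV
#'
#' Reads a delimited file into the canonical schema. Header names are matched
#' case-insensitively; `column_map` renames non-canonical headers
#' (`c(file_column = "canonical_name")`). Empty cells and the tokens `NA` and
#' `no answer` are read as missing. Unparseable or out-of-range cells become
#' missing values with a single counted warning; only an absent `year` or
#' `ward` column is an error.
#'
#' @param path path to the CSV file.
#' @param sep field delimiter (default comma).
#' @param column_map optional named character vector mapping file headers to
#'   canonical names.
#' @return A [survey_dataset()].
#' @export
read_survey <- function(path, sep = ",", column_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), "postopsat_io_error")
  }
  raw <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  if (!is.null(column_map)) {
    names(column_map) <- tolower(names(column_map))
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- unname(column_map[names(raw)[hit]])
  }
  survey_dataset(raw, provenance = path)
}

#' Write a questionnaire CSV
#'
#' Writes the canonical comma-delimited UTF-8 layout; missing values become
#' empty cells. `read_survey(write_survey(d, f))` reproduces `d`
#' field-for-field, including missingness.
#'
#' @param dataset a [survey_dataset()].
#' @param path output file path.
#' @export
write_survey <- function(dataset, path) {
  d <- as.data.frame(dataset)[, survey_fields(), drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(d, path, row.names = FALSE, na = "", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("cannot write ", path, ": ", conditionMessage(ok)),
          "postopsat_io_error")
  }
  invisible(path)
}

# Quality control --------------------------------------------------------------

#' Fraction of missing in-scope fields of a record
#'
#' @param record a single record (list or one-row data frame) or a
#'   `survey_dataset` (then the result is vectorised over rows).
#' @param fields the fields that count towards missingness; defaults to every
#'   canonical field except `year` and `ward`.
#' @return Numeric fraction(s) in `[0, 1]`.
#' @examples
#' missingness_fraction(list(age = NA, gender = "male"), c("age", "gender"))
#' @export
missingness_fraction <- function(record, fields = missingness_fields()) {
  if (length(fields) == 0L) {
    abort("fields must be non-empty", "postopsat_argument_error")
  }
  if (is.data.frame(record)) {
    absent <- setdiff(fields, names(record))
    for (f in absent) record[[f]] <- NA
    m <- is.na(as.matrix(record[, fields, drop = FALSE]))
    return(unname(rowMeans(m)))
  }
  record <- as.list(record)
  miss <- vapply(fields, function(f) {
    is.null(record[[f]]) || all(is.na(record[[f]]))
  }, logical(1))
  mean(miss)
}

# per-record missingness with the conditional scope: for respondents who
# answered "no" to the surgery question, the surgical fields are structurally
# inapplicable and are dropped from that record's scope.
record_missingness <- function(dataset, fields = missingness_fields(),
                               conditional = TRUE) {
  d <- as.data.frame(dataset)
  frac <- missingness_fraction(d, fields)
  if (conditional && "q1_surgery" %in% names(d)) {
    reduced <- setdiff(fields, surgical_fields())
    no_surgery <- !is.na(d$q1_surgery) & d$q1_surgery == "no"
    if (any(no_surgery) && length(reduced)) {
      frac[no_surgery] <-
        missingness_fraction(d[no_surgery, , drop = FALSE], reduced)
    }
  }
  frac
}

#' Discard questionnaires with too many missing responses
#'
#' A record is excluded iff its missingness fraction is strictly greater than
#' `threshold` (default 0.20, the "over 20% missing" rule); a record at
#' exactly the threshold is retained. With `conditional = TRUE` (default) the
#' surgical fields ([surgical_fields()]) are dropped from the scope of records
#' that answered "no" to the surgery question, so structurally blank fields do
#' not count as non-response.
#'
#' @param dataset a [survey_dataset()].
#' @param threshold missingness fraction above which a record is discarded.
#' @param fields fields in scope; see [missingness_fraction()].
#' @param conditional drop structurally inapplicable fields from the scope of
#'   non-operated records?
#' @return A list of class `exclusion_result`: `retained` and `excluded`
#'   (both `survey_dataset`s; their row counts always sum to the input count)
#'   and `report` (a one-row data frame of counts).
#' @export
apply_exclusion <- function(dataset, threshold = 0.20,
                            fields = missingness_fields(),
                            conditional = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    abort("threshold must be a fraction in [0, 1]", "postopsat_argument_error")
  }
  d <- as.data.frame(dataset)
  frac <- record_missingness(d, fields, conditional)
  drop <- frac > threshold
  prov <- attr(dataset, "provenance") %||% "unknown"
  retained <- survey_dataset(d[!drop, , drop = FALSE], provenance = prov)
  excluded <- survey_dataset(d[drop, , drop = FALSE], provenance = prov)
  report <- data.frame(
    reason = "missingness_gt_threshold",
    threshold = threshold,
    n_input = nrow(d),
    n_retained = sum(!drop),
    n_excluded = sum(drop),
    stringsAsFactors = FALSE
  )
  structure(list(retained = retained, excluded = excluded, report = report),
            class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "Exclusion at >%.0f%% missing: %d in, %d retained, %d excluded\n",
    100 * r$threshold, r$n_input, r$n_retained, r$n_excluded))
  invisible(x)
}

#' Logical-consistency check of one record
#'
#' Shipped rule set: (a) the postoperative-care item answered although the
#' respondent reports no surgery (`Q2_WITHOUT_SURGERY`); (b) any clinical
#' surgical field (infection, complication, protocol, innovation, pain)
#' answered although the respondent reports no surgery
#' (`CLINICAL_WITHOUT_SURGERY`). An empty result means the record is
#' consistent.
#'
#' @param record a single record (list or one-row data frame).
#' @return Character vector of violation codes (possibly empty).
#' @examples
#' consistency_check(list(q1_surgery = "no", q2_postop_care = 5))
#' @export
consistency_check <- function(record) {
  record <- as.list(record)
  g <- function(f) if (is.null(record[[f]])) NA else record[[f]]
  codes <- character(0)
  if (!is.na(g("q1_surgery")) && g("q1_surgery") == "no") {
    if (!is.na(g("q2_postop_care"))) codes <- c(codes, "Q2_WITHOUT_SURGERY")
    clinical <- c("infection", "complication", "protocol", "innovation",
                  "pain")
    if (any(!vapply(clinical, function(f) is.na(g(f)), logical(1)))) {
      codes <- c(codes, "CLINICAL_WITHOUT_SURGERY")
    }
  }
  codes
}

#' Consistency flags for a whole dataset
#'
#' Vectorised version of [consistency_check()].
#'
#' @param dataset a [survey_dataset()].
#' @return Logical vector: `TRUE` where the record has at least one violation.
#' @export
consistency_flags <- function(dataset) {
  d <- as.data.frame(dataset)
  no_surgery <- !is.na(d$q1_surgery) & d$q1_surgery == "no"
  clinical <- c("infection", "complication", "protocol", "innovation", "pain")
  answered_clin <- rowSums(!is.na(as.matrix(d[, clinical, drop = FALSE]))) > 0
  unname(no_surgery & (!is.na(d$q2_postop_care) | answered_clin))
}
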