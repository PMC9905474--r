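# Cohort table schemas, readers/writers, and the serialized model spec.
#
# Three table kinds flow through the pipeline:
#   patients    - one row per patient: demographics, death date, last record
#   medications - one row per dose or administration interval
#   biomarkers  - one row per profiled sample: TMB + expression targets
# All dates are ISO-8601 calendar dates (YYYY-MM-DD); absent values are empty
# cells, never sentinel numbers.

IRS_GENES <- c("PD-1", "PD-L1", "ADAM12", "TOP2A")
IRS_FEATURES <- c("TMB", IRS_GENES)

cohort_schemas <- list(
  patients = list(
    required = c("patient_id", "age", "gender", "tumor_type",
                 "death_date", "last_record_date"),
    dates = c("death_date", "last_record_date"),
    numeric = "age"
  ),
  medications = list(
    required = c("patient_id", "agent", "class", "start_date", "end_date"),
    dates = c("start_date", "end_date"),
    numeric = character()
  ),
  biomarkers = list(
    required = c("patient_id", "sample_collection_date", "tmb"),
    dates = "sample_collection_date",
    numeric = "tmb"
  )
)

parse_iso_dates <- function(x, col, allow_na = TRUE) {
  raw <- as.character(x)
  blank <- is.na(raw) | raw == ""
  out <- as.Date(rep(NA_character_, length(raw)))
  # strict format; a well-formed string can still be an invalid date (2020-02-30)
  shaped <- grepl("^\\d{4}-\\d{2}-\\d{2}$", raw[!blank])
  parsed_all <- suppressWarnings(as.Date(raw[!blank], format = "%Y-%m-%d"))
  parsed_all[!shaped] <- as.Date(NA)
  bad <- which(!blank)[is.na(parsed_all)]
  if (length(bad) > 0) {
    irs_abort(
      sprintf(
        "column '%s' has unparseable ISO-8601 date%s at row%s %s",
        col, if (length(bad) > 1) "s" else "", if (length(bad) > 1) "s" else "",
        paste(utils::head(bad, 10), collapse = ", ")
      ),
      "irscore_parse_error"
    )
  }
  out[!blank] <- parsed_all
  if (!allow_na && any(blank)) {
    irs_abort(
      sprintf("column '%s' must not contain empty dates (rows %s)",
              col, paste(utils::head(which(blank), 10), collapse = ", ")),
      "irscore_parse_error"
    )
  }
  out
}

#' Read a cohort table
#'
#' Reads one of the three cohort table kinds from a delimited text file.
#' The delimiter is chosen from the file extension (`.tsv`/`.txt` gives tab,
#' anything else comma). Dates must be ISO-8601 (`YYYY-MM-DD`); empty cells
#' are absent values. The header is validated against the documented schema
#' and errors name the offending column or row.
#'
#' @param path Path to a CSV/TSV file.
#' @param schema One of `"patients"`, `"medications"`, `"biomarkers"`.
#' @return A tibble with typed columns; row order preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "patient_id,age,gender,tumor_type,death_date,last_record_date",
#'   "P1,64,F,NSCLC,,2021-06-30"
#' ), f)
#' read_cohort(f, "patients")
read_cohort <- function(path, schema = c("patients", "medications", "biomarkers")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    irs_abort(sprintf("file not found: %s", path), "irscore_io_error")
  }
  sc <- cohort_schemas[[schema]]
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  assert_columns(raw, sc$required, sprintf("%s table '%s'", schema, path))
  out <- raw
  for (col in sc$dates) {
    out[[col]] <- parse_iso_dates(raw[[col]], col)
  }
  mandatory_dates <- switch(schema,
    patients = "last_record_date",
    medications = c("start_date", "end_date"),
    biomarkers = "sample_collection_date"
  )
  for (col in mandatory_dates) {
    if (anyNA(out[[col]])) {
      irs_abort(
        sprintf("column '%s' must be present for every row (rows %s)",
                col, paste(utils::head(which(is.na(out[[col]])), 10), collapse = ", ")),
        "irscore_schema_error"
      )
    }
  }
  num_cols <- sc$numeric
  if (schema == "biomarkers") {
    # every non-key column is an expression target (or housekeeping) count/level
    num_cols <- union(num_cols, setdiff(names(out), c("patient_id", "sample_collection_date")))
  }
  for (col in num_cols) {
    val <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & out[[col]] != "" & is.na(val))
    if (length(bad) > 0) {
      irs_abort(
        sprintf("column '%s' has non-numeric values at rows %s",
                col, paste(utils::head(bad, 10), collapse = ", ")),
        "irscore_parse_error"
      )
    }
    val[out[[col]] == ""] <- NA_real_
    out[[col]] <- val
  }
  validate_cohort(out, schema)
  irs_log("read %d %s rows from %s", nrow(out), schema, path)
  out
}

validate_cohort <- function(tbl, schema) {
  if (schema == "patients" && anyDuplicated(tbl$patient_id) > 0) {
    irs_abort("patient_id must be unique within a patients table",
              "irscore_schema_error")
  }
  if (schema == "medications" && any(tbl$end_date < tbl$start_date)) {
    bad <- which(tbl$end_date < tbl$start_date)
    irs_abort(
      sprintf("end_date precedes start_date at rows %s",
              paste(utils::head(bad, 10), collapse = ", ")),
      "irscore_schema_error"
    )
  }
  invisible(tbl)
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: dates are serialized as ISO-8601, absent
#' values as empty cells. `write_cohort()` then `read_cohort()` is the
#' identity on typed records.
#'
#' @param tbl A cohort tibble as returned by [read_cohort()] or the
#'   synthetic generator.
#' @param path Output file path; extension picks the delimiter.
#' @param schema Table kind, as in [read_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(tbl, path, schema = c("patients", "medications", "biomarkers")) {
  schema <- match.arg(schema)
  assert_columns(tbl, cohort_schemas[[schema]]$required, sprintf("%s table", schema))
  out <- tbl
  for (col in names(out)) {
    if (inherits(out[[col]], "Date")) {
      out[[col]] <- ifelse(is.na(out[[col]]), "", format(out[[col]], "%Y-%m-%d"))
    }
  }
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Load (or fetch the packaged) IRS model specification
#'
#' The model spec is a JSON document carrying everything needed to score a
#' patient deterministically: the locked coefficients, the High/Low
#' threshold, frozen per-gene centering medians (nRPM), the TMB floor used
#' inside the log2 transform, the TMB-High cutoff, and the housekeeping
#' reference RPM table used by [normalize_nrpm()]. With `path = NULL` the
#' packaged default spec is returned; it carries the published coefficients
#' (e.g. TMB 0.273758) and threshold 0.873569.
#'
#' @param path Path to a model-spec JSON file, or `NULL` for the packaged
#'   default.
#' @return An object of class `irs_model_spec`: a list with elements
#'   `coefficients`, `threshold`, `gene_medians`, `tmb_floor`,
#'   `tmb_high_cutoff`, `reference_rpm`.
#' @export
#' @examples
#' spec <- load_model_spec()
#' spec$coefficients[["TMB"]]
#' spec$threshold
load_model_spec <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "irs_model_spec.json", package = "irscore")
  }
  if (!file.exists(path)) {
    irs_abort(sprintf("model spec not found: %s", path), "irscore_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("coefficients", "threshold", "gene_medians", "tmb_floor", "tmb_high_cutoff")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    irs_abort(sprintf("model spec missing keys: %s", paste(missing, collapse = ", ")),
              "irscore_spec_error")
  }
  coefs <- unlist(raw$coefficients)
  missing_coef <- setdiff(IRS_FEATURES, names(coefs))
  if (length(missing_coef) > 0) {
    irs_abort(
      sprintf("model spec missing coefficient%s: %s",
              if (length(missing_coef) > 1) "s" else "",
              paste(missing_coef, collapse = ", ")),
      "irscore_spec_error"
    )
  }
  spec <- list(
    coefficients = coefs,
    threshold = as.numeric(raw$threshold),
    gene_medians = unlist(raw$gene_medians),
    tmb_floor = as.numeric(raw$tmb_floor),
    tmb_high_cutoff = as.numeric(raw$tmb_high_cutoff),
    reference_rpm = if (!is.null(raw$reference_rpm)) unlist(raw$reference_rpm) else NULL
  )
  stopifnot(is.finite(spec$threshold), spec$tmb_floor > 0, spec$tmb_high_cutoff > 0)
  class(spec) <- "irs_model_spec"
  spec
}

#' @export
print.irs_model_spec <- function(x, ...) {
  cat("IRS model specification\n")
  cat("  coefficients:\n")
  for (nm in names(x$coefficients)) {
    cat(sprintf("    %-7s % .6f\n", nm, x$coefficients[[nm]]))
  }
  cat(sprintf("  threshold (High >=): %.6f\n", x$threshold))
  cat(sprintf("  TMB floor %.2f Muts/Mb; TMB-High cutoff %.1f Muts/Mb\n",
              x$tmb_floor, x$tmb_high_cutoff))
  invisible(x)
}

#' Default anti-neoplastic agent classification table
#'
#' The agent -> class dictionary is user-supplied configuration; this
#' packaged default covers the synthetic agents produced by
#' [gen_treatment_history()] plus common real examples. Classes follow the
#' field's grouping: chemotherapy, PD-1, PD-L1, CTLA4, oncogene TKI,
#' hormonal, other.
#'
#' @return A tibble with columns `agent`, `class`.
#' @export
default_agent_classes <- function() {
  path <- system.file("extdata", "agent_classes.csv", package = "irscore")
  readr::read_csv(path, col_types = "cc", progress = FALSE)
}

#' Read a key-value configuration file
#'
#' Plain YAML mapping of option names to values (e.g. line-rule overrides,
#' generator settings).
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    irs_abort(sprintf("config file not found: %s", path), "irscore_io_error")
  }
  yaml::read_yaml(path)
}
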