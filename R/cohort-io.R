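#' @title Cohort data model and delimited-text I/O
#'
#' @description
#' A cohort is a pair of tables: one row per patient with covariates measured
#' at AF diagnosis, and one row per (patient, endpoint) with follow-up time in
#' days and an event indicator. History and treatment flags are tri-state:
#' `TRUE`, `FALSE`, or `NA` (unknown). The distinction between `FALSE` and
#' `NA` matters — missingness accounting and complete-case analysis depend on
#' it — so files use an empty cell as the single missing sentinel and readers
#' never coerce blanks to `FALSE`.
#'
#' Calendar dates never enter the package: the data preparer resolves index
#' and event dates to `time_days` beforehand.
#'
#' @name cohort-io
NULL

af_outcome_cols <- function() {
  eps <- af_endpoints()
  c(rbind(paste0("time_", eps), paste0("event_", eps)))
}

af_required_cols <- function() {
  c("patient_id", "age", "sex", af_outcome_cols())
}

new_af_cohort <- function(patients, outcomes) {
  structure(list(patients = patients, outcomes = outcomes),
            class = "af_cohort")
}

#' @export
print.af_cohort <- function(x, ...) {
  cat(sprintf("<af_cohort> %d patients, %d outcome records (%s)\n",
              nrow(x$patients), nrow(x$outcomes),
              paste(af_endpoints(), collapse = ", ")))
  invisible(x)
}

# parse "true"/"false"/"1"/"0" (any case) to logical, empty -> NA
af_parse_flag <- function(x, col) {
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "TRUE", "True", "T")] <- TRUE
  out[x %in% c("0", "false", "FALSE", "False", "F")] <- FALSE
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    af_abort(sprintf("column '%s': unparseable flag value '%s' at row %d",
                     col, x[which(bad)[1]], which(bad)[1]),
             class = "af_error_parse")
  }
  out
}

af_parse_num <- function(x, col) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    af_abort(sprintf("column '%s': unparseable numeric '%s' at row %d",
                     col, x[which(bad)[1]], which(bad)[1]),
             class = "af_error_parse")
  }
  out
}

#' Read a cohort table
#'
#' Reads a delimited text file (CSV, or TSV by extension) with one row per
#' patient into an [`af_cohort`][cohort-io]. Empty cells are the missing
#' sentinel for every optional field; blank flags stay `NA`, never `FALSE`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the column names used in the file (values), for cohorts
#'   exported under a different dictionary.
#' @param sep Field separator; inferred from the extension when `NULL`
#'   (`.tsv`/`.txt` use tab, otherwise comma).
#' @return An `af_cohort`: list with `patients` (one row per patient) and
#'   `outcomes` (one row per patient and endpoint, columns `patient_id`,
#'   `endpoint`, `time_days`, `event`).
#' @export
read_cohort <- function(path, schema = NULL, sep = NULL) {
  if (!file.exists(path)) af_abort(sprintf("no such file: %s", path),
                                   class = "af_error_io")
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, quote = "\"",
                           fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      idx <- match(schema[[canon]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- canon
    }
  }
  missing_cols <- setdiff(af_required_cols(), names(raw))
  if (length(missing_cols)) {
    af_abort(sprintf("missing mandatory column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             class = "af_error_schema")
  }

  n <- nrow(raw)
  blank_na <- function(x) { x <- trimws(x); x[x == ""] <- NA; x }
  patients <- data.frame(patient_id = blank_na(raw$patient_id),
                         stringsAsFactors = FALSE)
  if (anyNA(patients$patient_id) || anyDuplicated(patients$patient_id)) {
    af_abort("patient_id must be present and unique",
             class = "af_error_schema")
  }
  patients$sex <- blank_na(raw$sex)
  bad_sex <- !is.na(patients$sex) & !patients$sex %in% c("female", "male")
  if (any(bad_sex)) {
    af_abort(sprintf("invalid sex value '%s' at row %d",
                     patients$sex[which(bad_sex)[1]], which(bad_sex)[1]),
             class = "af_error_parse")
  }
  if ("ethnicity" %in% names(raw)) {
    eth <- blank_na(raw$ethnicity)
    bad <- !is.na(eth) & !eth %in% c("white", "asian", "black_mixed_other")
    if (any(bad)) {
      af_abort(sprintf("invalid ethnicity '%s' at row %d",
                       eth[which(bad)[1]], which(bad)[1]),
               class = "af_error_parse")
    }
    patients$ethnicity <- eth
  } else {
    patients$ethnicity <- rep(NA_character_, n)
  }
  for (col in af_numeric_fields()) {
    patients[[col]] <- if (col %in% names(raw)) {
      af_parse_num(raw[[col]], col)
    } else rep(NA_real_, n)
  }
  for (col in af_flag_fields()) {
    patients[[col]] <- if (col %in% names(raw)) {
      af_parse_flag(raw[[col]], col)
    } else rep(NA, n)
  }

  validate_patients(patients)

  outcomes <- do.call(rbind, lapply(af_endpoints(), function(ep) {
    tm <- af_parse_num(raw[[paste0("time_", ep)]], paste0("time_", ep))
    ev <- af_parse_num(raw[[paste0("event_", ep)]], paste0("event_", ep))
    data.frame(patient_id = patients$patient_id, endpoint = ep,
               time_days = tm, event = as.integer(ev),
               stringsAsFactors = FALSE)
  }))
  rownames(outcomes) <- NULL
  validate_outcomes(outcomes)
  new_af_cohort(patients, outcomes)
}

validate_patients <- function(patients) {
  bad_age <- is.na(patients$age) | patients$age < 18
  if (any(bad_age)) {
    af_abort(sprintf(
      "cohort restricted to adults (age >= 18); offending patient_id(s): %s",
      paste(utils::head(patients$patient_id[bad_age], 5), collapse = ", ")),
      class = "af_error_validate")
  }
  chk <- function(ok, what) {
    if (any(!ok, na.rm = TRUE)) {
      af_abort(sprintf("%s; offending patient_id(s): %s", what,
                       paste(utils::head(
                         patients$patient_id[which(!ok)], 5), collapse = ", ")),
               class = "af_error_validate")
    }
  }
  chk(patients$height > 0 & patients$height < 2.6,
      "height must be in metres within (0, 2.6)")
  chk(patients$weight > 0, "weight must be positive")
  chk(patients$pulse > 0, "pulse must be positive")
  chk(patients$sbp > patients$dbp & patients$dbp > 0,
      "require sbp > dbp > 0")
  full <- !is.na(patients$oac) & !is.na(patients$noac) & !is.na(patients$vka)
  bad_oac <- full & (patients$oac != (patients$noac | patients$vka))
  chk(!bad_oac, "oac must equal (noac OR vka) when all three are recorded")
  invisible(patients)
}

validate_outcomes <- function(outcomes) {
  if (any(is.na(outcomes$time_days) | outcomes$time_days < 0)) {
    af_abort("outcome time_days must be present and >= 0",
             class = "af_error_validate")
  }
  if (!all(outcomes$event %in% c(0L, 1L))) {
    af_abort("outcome event indicator must be 0 or 1",
             class = "af_error_validate")
  }
  if (anyDuplicated(outcomes[c("patient_id", "endpoint")])) {
    af_abort("exactly one outcome record per (patient, endpoint)",
             class = "af_error_validate")
  }
  invisible(outcomes)
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: one row per patient, endpoint follow-up
#' expanded into `time_*`/`event_*` columns, missing values as empty cells.
#'
#' @param cohort An `af_cohort`.
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "af_cohort"))
  out <- cohort$patients
  out[af_flag_fields()] <- lapply(out[af_flag_fields()],
                                  function(x) ifelse(is.na(x), "",
                                                     ifelse(x, "1", "0")))
  for (ep in af_endpoints()) {
    oc <- cohort$outcomes[cohort$outcomes$endpoint == ep, ]
    idx <- match(out$patient_id, oc$patient_id)
    out[[paste0("time_", ep)]] <- oc$time_days[idx]
    out[[paste0("event_", ep)]] <- oc$event[idx]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run configuration for a validation analysis
#'
#' @param horizons Horizons in months at which every model is evaluated
#'   (intersected with each model's own horizons). Default `c(1, 12, 24)`.
#' @param n_quantiles Number of equal-frequency calibration bins; default 5
#'   (quintiles).
#' @param auc_method Censoring handling for the horizon AUC: `"exclude"`
#'   (status-based; patients censored event-free before the horizon are
#'   dropped) or `"ipcw"` (inverse-probability-of-censoring weights).
#' @param subgroups Character vector of subgroup analyses to run, any of
#'   `"oac"`, `"stroke_stratum"`, `"bleed_stratum"`.
#' @param min_stratum Minimum subgroup size; smaller strata are skipped with
#'   a log entry. Default 50.
#' @param min_bin Minimum calibration-bin size. Default 20.
#' @param seed Seed for any resampling-based procedure.
#' @param days_per_month Month-to-day conversion constant.
#' @return An object of class `af_config`.
#' @export
validation_config <- function(horizons = c(1, 12, 24), n_quantiles = 5,
                              auc_method = c("exclude", "ipcw"),
                              subgroups = c("oac", "stroke_stratum",
                                            "bleed_stratum"),
                              min_stratum = 50, min_bin = 20, seed = 1L,
                              days_per_month = 30.4375) {
  auc_method <- match.arg(auc_method)
  stopifnot(length(horizons) >= 1, all(horizons > 0),
            !is.unsorted(horizons, strictly = TRUE),
            n_quantiles >= 2, min_stratum >= 1)
  structure(list(horizons = horizons, n_quantiles = n_quantiles,
                 auc_method = auc_method, subgroups = subgroups,
                 min_stratum = min_stratum, min_bin = min_bin,
                 seed = as.integer(seed), days_per_month = days_per_month),
            class = "af_config")
}
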