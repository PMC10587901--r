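#' Convert horizons in months to days
#'
#' Risk-equation horizons are quoted in months; follow-up times are in days.
#' The conversion uses the mean Gregorian month, 30.4375 days, so that
#' 12 months = 365.25 days and 24 months = 730.5 days exactly.
#'
#' @param months Numeric vector of horizons in months.
#' @param days_per_month Days per month; default 30.4375.
#' @return Numeric vector of horizons in days.
#' @export
#' @examples
#' months_to_days(c(1, 12, 24))
months_to_days <- function(months, days_per_month = 30.4375) {
  stopifnot(is.numeric(months), all(months > 0))
  months * days_per_month
}

# classed error helper: metric code signals conditions the pipeline can catch
# per cell instead of aborting the whole run
af_abort <- function(msg, class = "af_error", ...) {
  stop(errorCondition(msg, ..., class = c(class, "af_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# safe lookup in a named vector/list with a default for absent names
af_get <- function(x, name, default) {
  if (!name %in% names(x)) return(default)
  v <- x[[name]]
  if (is.null(v) || (length(v) == 1 && is.na(v))) default else v
}

# endpoints recognised throughout the package
af_endpoints <- function() c("death", "stroke_se", "major_bleed")

# tri-state history/treatment flags of a patient record
af_flag_fields <- function() {
  c("chf", "hypertension", "diabetes", "prior_stroke_tia", "vascular_disease",
    "peripheral_vascular_disease", "carotid_occlusive_disease",
    "bleeding_history", "ckd_grade3plus", "cirrhosis", "current_smoker",
    "sleep_apnoea", "dementia", "paroxysmal_af", "abnormal_renal_function",
    "abnormal_liver_function", "labile_inr",
    "oac", "noac", "vka", "antiplatelet_or_nsaid")
}

af_numeric_fields <- function() {
  c("age", "pulse", "sbp", "dbp", "weight", "height",
    "alcohol_units_per_week")
}

# covariate names a risk-model term may reference (raw fields plus the
# indicators derived from sex and ethnicity)
af_model_covariates <- function() {
  c(af_numeric_fields(), af_flag_fields(), "female",
    "ethnicity_asian", "ethnicity_black_mixed_other")
}

# resolve a model covariate to a numeric vector over the patient table
af_covariate_values <- function(patients, covariate) {
  switch(covariate,
    female = as.numeric(patients$sex == "female"),
    ethnicity_asian = as.numeric(patients$ethnicity == "asian"),
    ethnicity_black_mixed_other =
      as.numeric(patients$ethnicity == "black_mixed_other"),
    {
      v <- patients[[covariate]]
      if (is.null(v)) af_abort(sprintf("unknown covariate '%s'", covariate),
                               class = "af_error_covariate")
      as.numeric(v)
    }
  )
}
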