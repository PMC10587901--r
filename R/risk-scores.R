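#' @title Point scores and risk-equation predictions
#'
#' @description
#' Two families of predictors are computed per patient: integer point scores
#' (CHA2DS2-VASc for stroke, HAS-BLED for bleeding) and coefficient-driven
#' Cox risk equations loaded as [`af_model_spec`][new_model_spec] objects.
#'
#' Missingness is handled asymmetrically, on purpose. Point scores are
#' computable for everyone: a missing component contributes 0 points and the
#' result is flagged `complete = FALSE`. Risk equations never impute — a
#' patient missing any required covariate is *not evaluable* and gets `NA`,
#' which is what drives the missingness accounting of the validation
#' pipeline.
#'
#' @name risk-scores
NULL

af_patients <- function(x) {
  if (inherits(x, "af_cohort")) x$patients else x
}

#' CHA2DS2-VASc stroke risk score
#'
#' Standard published weights: congestive heart failure +1, hypertension +1,
#' age >= 75 +2, diabetes +1, prior stroke/TIA +2, vascular disease +1,
#' age 65-74 +1, female sex +1. Range 0-9. Missing history flags score 0 and
#' set `complete = FALSE`; a missing age or sex makes the score itself `NA`.
#'
#' @param x An `af_cohort` or patient data frame.
#' @return A data frame of class `af_point_score`: `patient_id`, one column
#'   of awarded points per component, `score`, `complete`.
#' @export
chads_vasc <- function(x) {
  p <- af_patients(x)
  comp <- data.frame(
    chf = 1 * (p$chf %in% TRUE),
    hypertension = 1 * (p$hypertension %in% TRUE),
    age_ge75 = 2 * (!is.na(p$age) & p$age >= 75),
    diabetes = 1 * (p$diabetes %in% TRUE),
    prior_stroke_tia = 2 * (p$prior_stroke_tia %in% TRUE),
    vascular_disease = 1 * (p$vascular_disease %in% TRUE),
    age_65_74 = 1 * (!is.na(p$age) & p$age >= 65 & p$age < 75),
    female = 1 * (!is.na(p$sex) & p$sex == "female")
  )
  complete <- !is.na(p$age) & !is.na(p$sex) &
    !is.na(p$chf) & !is.na(p$hypertension) & !is.na(p$diabetes) &
    !is.na(p$prior_stroke_tia) & !is.na(p$vascular_disease)
  score <- as.integer(rowSums(comp))
  score[is.na(p$age) | is.na(p$sex)] <- NA_integer_
  out <- cbind(data.frame(patient_id = p$patient_id,
                          stringsAsFactors = FALSE),
               comp, score = score, complete = complete)
  class(out) <- c("af_point_score", "data.frame")
  attr(out, "score_name") <- "chads_vasc"
  out
}

#' HAS-BLED bleeding risk score
#'
#' One point each for: uncontrolled hypertension, abnormal renal function,
#' abnormal liver function, prior stroke, bleeding history, age > 65,
#' antiplatelet/NSAID use, alcohol excess, and — only when
#' `include_labile_inr = TRUE` — labile INR. Primary-care baseline records
#' rarely carry an INR history, so the default is the labile-INR-free
#' variant, whose maximum attainable score is 8 rather than 9.
#'
#' Hypertension is operationalised as SBP > `uncontrolled_sbp` when SBP is
#' recorded, falling back to the hypertension-history flag otherwise; alcohol
#' excess is > `alcohol_threshold` units/week. Both cut-offs are
#' configurable. Missing components score 0 with `complete = FALSE`; missing
#' age makes the score `NA`.
#'
#' @inheritParams chads_vasc
#' @param include_labile_inr Include the labile-INR component (full 0-9
#'   score)? Default `FALSE` (modified 0-8 score).
#' @param uncontrolled_sbp SBP cut-off in mmHg for uncontrolled
#'   hypertension; default 160.
#' @param alcohol_threshold Units/week above which alcohol counts; default 8.
#' @return A data frame of class `af_point_score` (see [chads_vasc()]).
#' @export
has_bled <- function(x, include_labile_inr = FALSE, uncontrolled_sbp = 160,
                     alcohol_threshold = 8) {
  p <- af_patients(x)
  htn_known <- !is.na(p$sbp) | !is.na(p$hypertension)
  htn <- ifelse(!is.na(p$sbp), p$sbp > uncontrolled_sbp,
                p$hypertension %in% TRUE)
  comp <- data.frame(
    hypertension_uncontrolled = 1 * (htn %in% TRUE),
    abnormal_renal = 1 * (p$abnormal_renal_function %in% TRUE),
    abnormal_liver = 1 * (p$abnormal_liver_function %in% TRUE),
    prior_stroke = 1 * (p$prior_stroke_tia %in% TRUE),
    bleeding_history = 1 * (p$bleeding_history %in% TRUE),
    age_gt65 = 1 * (!is.na(p$age) & p$age > 65),
    antiplatelet_or_nsaid = 1 * (p$antiplatelet_or_nsaid %in% TRUE),
    alcohol_excess = 1 * (!is.na(p$alcohol_units_per_week) &
                            p$alcohol_units_per_week > alcohol_threshold)
  )
  complete <- !is.na(p$age) & htn_known &
    !is.na(p$abnormal_renal_function) & !is.na(p$abnormal_liver_function) &
    !is.na(p$prior_stroke_tia) & !is.na(p$bleeding_history) &
    !is.na(p$antiplatelet_or_nsaid) & !is.na(p$alcohol_units_per_week)
  if (include_labile_inr) {
    comp$labile_inr <- 1 * (p$labile_inr %in% TRUE)
    complete <- complete & !is.na(p$labile_inr)
  }
  score <- as.integer(rowSums(comp))
  score[is.na(p$age)] <- NA_integer_
  out <- cbind(data.frame(patient_id = p$patient_id,
                          stringsAsFactors = FALSE),
               comp, score = score, complete = complete)
  class(out) <- c("af_point_score", "data.frame")
  attr(out, "score_name") <- if (include_labile_inr) "has_bled_full"
    else "has_bled"
  out
}

#' Stroke risk stratum from a CHA2DS2-VASc score
#'
#' Low = 0, moderate = 1, high >= 2: the granularity at which incident-AF
#' cohorts are conventionally reported.
#'
#' @param score Integer vector of CHA2DS2-VASc scores in 0-9 (`NA` allowed).
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
stroke_risk_stratum <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 9)))
    af_abort("CHA2DS2-VASc score out of range [0, 9]",
             class = "af_error_validate")
  factor(ifelse(score == 0, "low", ifelse(score == 1, "moderate", "high")),
         levels = c("low", "moderate", "high"))
}

#' Bleeding risk stratum from a HAS-BLED score
#'
#' Lower if score < 2, higher if score >= 2. Published subgrouping language
#' ("< 2 or > 2") leaves the score of exactly 2 unassigned; this package
#' assigns it to the higher stratum and says so in a message the first time
#' it happens.
#'
#' @param score Integer vector of HAS-BLED scores in 0-9 (`NA` allowed).
#' @return Factor with levels `lower`, `higher`.
#' @export
bleed_risk_stratum <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 9)))
    af_abort("HAS-BLED score out of range [0, 9]",
             class = "af_error_validate")
  if (any(score == 2, na.rm = TRUE))
    message("bleed_risk_stratum: scores equal to 2 assigned to 'higher' ",
            "(the conventional '<2 or >2' split leaves 2 unstated)")
  factor(ifelse(score < 2, "lower", "higher"),
         levels = c("lower", "higher"))
}

#' Centered linear predictor of a risk equation
#'
#' Evaluates `lp = sum_j beta_j (t_j(x_j) - t_j(xref_j))` over a patient
#' table. Patients missing any required covariate are returned not-evaluable
#' (`lp = NA`): values are never imputed.
#'
#' @param x An `af_cohort` or patient data frame.
#' @param spec An [`af_model_spec`][new_model_spec].
#' @return Data frame `patient_id`, `lp`, `evaluable`.
#' @export
linear_predictor <- function(x, spec) {
  stopifnot(inherits(spec, "af_model_spec"))
  p <- af_patients(x)
  n <- nrow(p)
  lp <- numeric(n)
  evaluable <- rep(TRUE, n)
  precentered <- identical(spec$centering, "precentered")
  for (tm in spec$terms) {
    v <- af_covariate_values(p, tm$covariate)
    tv <- af_apply_transform(v, tm, p$patient_id)
    evaluable <- evaluable & !is.na(tv)
    contrib <- tm$beta * tv
    if (!precentered) {
      xref <- if (tm$covariate %in% names(spec$centering))
        spec$centering[[tm$covariate]] else 0
      contrib <- contrib - tm$beta * af_apply_transform(xref, tm, "xref")
    }
    lp <- lp + ifelse(is.na(contrib), 0, contrib)
  }
  lp[!evaluable] <- NA_real_
  data.frame(patient_id = p$patient_id, lp = lp, evaluable = evaluable,
             stringsAsFactors = FALSE)
}

#' Predicted risk from a linear predictor
#'
#' The Cox survival transform `risk = 1 - S0(horizon)^exp(lp)`: strictly
#' increasing in `lp` whenever `S0 < 1`, equal to `1 - S0` at `lp = 0`, and
#' identically 0 under zero baseline hazard (`S0 = 1`).
#'
#' @param lp Numeric vector of centered linear predictors (`NA` for
#'   not-evaluable patients).
#' @param spec An `af_model_spec` with a baseline survival tabulated at
#'   `horizon`.
#' @param horizon Horizon in months.
#' @return Numeric vector of risks in `[0, 1)`.
#' @export
predicted_risk <- function(lp, spec, horizon) {
  s0 <- s0_at(spec, horizon)
  1 - s0^exp(lp)
}

#' Batch predictions for several models and horizons
#'
#' @param x An `af_cohort` or patient data frame.
#' @param specs List of `af_model_spec` objects.
#' @param horizons Horizons in months; each model is evaluated at the
#'   intersection with its own horizons. `NULL` uses each model's horizons.
#' @return Data frame with one row per (patient, model, horizon):
#'   `patient_id`, `model_id`, `outcome`, `horizon`, `lp`, `risk`,
#'   `evaluable`.
#' @export
score_cohort <- function(x, specs, horizons = NULL) {
  if (inherits(specs, "af_model_spec")) specs <- list(specs)
  rows <- lapply(specs, function(spec) {
    hz <- if (is.null(horizons)) spec$horizons
      else intersect(horizons, spec$horizons)
    if (!length(hz)) return(NULL)
    lp <- linear_predictor(x, spec)
    do.call(rbind, lapply(hz, function(h) {
      data.frame(patient_id = lp$patient_id, model_id = spec$model_id,
                 outcome = spec$outcome, horizon = h, lp = lp$lp,
                 risk = predicted_risk(lp$lp, spec, h),
                 evaluable = lp$evaluable, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
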