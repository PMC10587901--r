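#' @title Coefficient-driven Cox risk equations
#'
#' @description
#' A risk-model specification is the transcription of a published Cox risk
#' equation: a set of terms (covariate, transform, coefficient), centering
#' metadata, and a baseline survival probability per horizon. The predicted
#' risk of the event by horizon `t` is
#' \deqn{r(x, t) = 1 - S_0(t)^{\exp(lp)}}
#' where `lp` is the centered linear predictor. Coefficients are inputs —
#' transcribed from the publication that fitted them — never re-derived here.
#'
#' Supported term transforms:
#' \describe{
#'   \item{`linear`}{the covariate value itself.}
#'   \item{`log`}{natural log; evaluation fails loudly on non-positive
#'     values.}
#'   \item{`linear_spline`}{`max(0, x - knot)`, the hinge basis of a
#'     piecewise-linear (linear-spline) term; field `knot`.}
#'   \item{`indicator_gt`}{`1` if `x > threshold` else `0`; field
#'     `threshold`.}
#' }
#' The machine-checkable schema of the JSON coefficient file ships at
#' `system.file("extdata", "model-spec-schema.json", package = "afvalidate")`.
#'
#' @name model-spec
NULL

af_transform_types <- function() {
  c("linear", "log", "linear_spline", "indicator_gt")
}

#' Construct and validate a risk-model specification
#'
#' @param model_id Identifier, e.g. `"garfield2017_death_reduced"`.
#' @param outcome One of `"death"`, `"stroke_se"`, `"major_bleed"`.
#' @param horizons Numeric vector of horizons in months, increasing.
#' @param terms List of terms; each a list with `covariate` (a patient-record
#'   field or derived indicator), `transform` (a list with `type` and any
#'   transform parameters), and `beta` (log-hazard-ratio per transformed
#'   unit).
#' @param centering Either the string `"precentered"` (coefficients already
#'   absorb the reference values) or a named list/vector of reference
#'   covariate values; the linear predictor subtracts each term evaluated at
#'   its reference (covariates absent from the map are referenced at 0).
#' @param baseline_survival Named list/vector mapping each horizon (months,
#'   as names) to the baseline survival probability S0 in (0, 1].
#' @return An object of class `af_model_spec`.
#' @export
new_model_spec <- function(model_id, outcome, horizons, terms, centering,
                           baseline_survival) {
  if (!is.character(model_id) || length(model_id) != 1 || !nzchar(model_id))
    af_abort("model_id must be a non-empty string", class = "af_error_spec")
  if (!outcome %in% af_endpoints())
    af_abort(sprintf("unknown outcome '%s'", outcome),
             class = "af_error_spec")
  horizons <- as.numeric(horizons)
  if (!length(horizons) || any(horizons <= 0) ||
      is.unsorted(horizons, strictly = TRUE))
    af_abort("horizons must be positive and strictly increasing",
             class = "af_error_spec")
  for (tm in terms) {
    if (is.null(tm$covariate) || is.null(tm$beta) ||
        is.null(tm$transform$type))
      af_abort("each term needs covariate, transform$type and beta",
               class = "af_error_spec")
    if (!tm$covariate %in% af_model_covariates())
      af_abort(sprintf("unknown covariate '%s' in model '%s'",
                       tm$covariate, model_id), class = "af_error_covariate")
    if (!tm$transform$type %in% af_transform_types())
      af_abort(sprintf("unknown transform type '%s'", tm$transform$type),
               class = "af_error_spec")
    if (tm$transform$type == "linear_spline" && is.null(tm$transform$knot))
      af_abort("linear_spline transform requires a knot",
               class = "af_error_spec")
    if (tm$transform$type == "indicator_gt" &&
        is.null(tm$transform$threshold))
      af_abort("indicator_gt transform requires a threshold",
               class = "af_error_spec")
  }
  precentered <- identical(centering, "precentered")
  if (!precentered) {
    centering <- unlist(centering)
    if (length(centering) &&
        !all(names(centering) %in% af_model_covariates()))
      af_abort("centering references an unknown covariate",
               class = "af_error_covariate")
  }
  s0 <- unlist(baseline_survival)
  hz_missing <- setdiff(as.character(horizons), names(s0))
  if (length(hz_missing))
    af_abort(sprintf("baseline_survival missing horizon(s): %s",
                     paste(hz_missing, collapse = ", ")),
             class = "af_error_spec")
  s0 <- s0[as.character(horizons)]
  if (any(s0 <= 0 | s0 > 1))
    af_abort("baseline survival must lie in (0, 1]", class = "af_error_spec")
  if (is.unsorted(rev(s0)))
    af_abort("baseline survival must be non-increasing in horizon",
             class = "af_error_spec")
  structure(list(model_id = model_id, outcome = outcome,
                 horizons = horizons, terms = terms,
                 centering = if (precentered) "precentered" else centering,
                 baseline_survival = s0),
            class = "af_model_spec")
}

#' @export
print.af_model_spec <- function(x, ...) {
  cat(sprintf("<af_model_spec> %s (%s), %d terms, horizons [%s] months\n",
              x$model_id, x$outcome, length(x$terms),
              paste(x$horizons, collapse = ", ")))
  invisible(x)
}

#' Read a risk-model coefficient file
#'
#' Loads a JSON coefficient file (one file per model generation and outcome)
#' and validates every invariant: baseline survival in (0, 1] and
#' non-increasing with horizon, every covariate name resolvable, transform
#' parameters present.
#'
#' @param path Path to a JSON file matching the shipped schema.
#' @return A validated [`af_model_spec`][new_model_spec].
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) af_abort(sprintf("no such file: %s", path),
                                   class = "af_error_io")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("model_id", "outcome", "horizons", "terms",
              "baseline_survival")) {
    if (is.null(raw[[f]]))
      af_abort(sprintf("model spec missing field '%s'", f),
               class = "af_error_spec")
  }
  new_model_spec(model_id = raw$model_id, outcome = raw$outcome,
                 horizons = unlist(raw$horizons), terms = raw$terms,
                 centering = raw$centering %||% "precentered",
                 baseline_survival = raw$baseline_survival)
}

#' Write a risk-model coefficient file
#'
#' @param spec An `af_model_spec`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "af_model_spec"))
  out <- list(model_id = spec$model_id, outcome = spec$outcome,
              horizons = spec$horizons, terms = spec$terms,
              centering = if (identical(spec$centering, "precentered"))
                "precentered" else as.list(spec$centering),
              baseline_survival = as.list(spec$baseline_survival))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# baseline survival at a horizon (months); error if not tabulated
s0_at <- function(spec, horizon) {
  s0 <- spec$baseline_survival[as.character(horizon)]
  if (is.na(s0))
    af_abort(sprintf("model '%s' has no baseline survival at %s months",
                     spec$model_id, horizon), class = "af_error_spec")
  unname(s0)
}

# evaluate one term's transform on a numeric vector (NA passes through);
# domain violations name the patient and term
af_apply_transform <- function(x, tm, ids) {
  tr <- tm$transform
  switch(tr$type,
    linear = x,
    log = {
      bad <- !is.na(x) & x <= 0
      if (any(bad))
        af_abort(sprintf(
          "log transform of non-positive %s for patient %s",
          tm$covariate, ids[which(bad)[1]]), class = "af_error_domain")
      log(x)
    },
    linear_spline = pmax(0, x - tr$knot),
    indicator_gt = as.numeric(x > tr$threshold)
  )
}
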