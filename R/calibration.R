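#' @title Calibration of predicted against observed horizon risk
#'
#' @description
#' Two complementary views. Calibration-in-the-large asks whether the
#' average predicted risk matches the observed risk: it is summarised by the
#' intercept of a logistic recalibration of horizon outcome status on an
#' offset of `logit(prediction)` (slope fixed at 1), so a positive intercept
#' means the model underpredicts. The calibration slope comes from the
#' un-offset logistic fit on `logit(prediction)`. Quantile calibration bins
#' patients into equal-frequency groups of predicted risk and compares each
#' bin's mean prediction with its Kaplan-Meier observed risk at the horizon —
#' the plot-ready view in which miscalibration that grows with predicted
#' risk shows up as a widening gap in the upper quantiles.
#'
#' @name calibration
NULL

#' Calibration-in-the-large and calibration slope
#'
#' Outcome status at the horizon is determined under the same exclusion rule
#' as the horizon AUC (event by horizon = 1; follow-up reaching the horizon
#' event-free = 0; censored early = excluded from the regressions). Because
#' dropping early-censored controls over-represents cases, the regressions
#' weight each retained patient by the inverse Kaplan-Meier censoring
#' survival at its status-determination time; with no censoring before the
#' horizon all weights are 1 and the fit is the plain offset-logistic
#' recalibration. The overall observed risk is the Kaplan-Meier estimate on
#' the full input, so censored patients still contribute to the headline
#' predicted-vs-observed comparison.
#'
#' @param predictions Predicted risks in `(0, 1)`; values at exactly 0 or 1
#'   are clipped to `[1e-6, 1 - 1e-6]` and counted.
#' @param times,events Follow-up in days and event indicators.
#' @param horizon Horizon in days.
#' @return Object of class `af_calibration`: `mean_predicted`,
#'   `km_observed`, `intercept` (logit units), `intercept_se`, `slope`,
#'   `slope_se`, `n`, `n_status` (patients entering the regressions),
#'   `n_clipped`.
#' @export
calibration_in_the_large <- function(predictions, times, events, horizon) {
  n <- length(predictions)
  stopifnot(length(times) == n, length(events) == n)
  if (anyNA(predictions))
    af_abort("predictions contain NA; restrict to evaluable patients",
             class = "af_error_validate")
  clip <- predictions <= 0 | predictions >= 1
  p <- pmin(pmax(predictions, 1e-6), 1 - 1e-6)
  status <- af_horizon_status(times, events, horizon)
  keep <- !is.na(status)
  y <- as.numeric(status[keep])
  if (length(unique(y)) < 2)
    af_abort("all patients share one horizon status; calibration not estimable",
             class = "af_error_degenerate")
  lp <- stats::qlogis(p[keep])
  # inverse-probability-of-censoring weights: retention probability is
  # G(T-) for a case, G(horizon-) for a control, with G the KM estimate of
  # the censoring survival; normalised to mean 1
  g_km <- kaplan_meier(times, 1 - events)
  g_at <- km_survival_at(g_km, pmin(times[keep], horizon) - 1e-9)
  if (any(g_at <= 0))
    af_abort("censoring survival zero before the horizon",
             class = "af_error_degenerate")
  w <- (1 / g_at) / mean(1 / g_at)
  fit_int <- suppressWarnings(
    stats::glm(y ~ 1 + offset(lp), family = stats::binomial(), weights = w))
  fit_slope <- suppressWarnings(
    stats::glm(y ~ lp, family = stats::binomial(), weights = w))
  km <- kaplan_meier(times, events)
  structure(list(
    mean_predicted = mean(predictions),
    km_observed = observed_risk(km, horizon),
    intercept = unname(stats::coef(fit_int)[1]),
    intercept_se = unname(sqrt(diag(stats::vcov(fit_int)))[1]),
    slope = unname(stats::coef(fit_slope)[2]),
    slope_se = unname(sqrt(diag(stats::vcov(fit_slope)))[2]),
    n = n, n_status = sum(keep), n_clipped = sum(clip)),
    class = "af_calibration")
}

#' @export
print.af_calibration <- function(x, ...) {
  cat(sprintf(
    "<af_calibration> mean predicted %.4f vs KM observed %.4f; intercept %.4f (se %.4f), slope %.4f (se %.4f), n=%d\n",
    x$mean_predicted, x$km_observed, x$intercept, x$intercept_se,
    x$slope, x$slope_se, x$n))
  invisible(x)
}

#' Quantile calibration table
#'
#' Equal-frequency binning of patients by predicted risk with deterministic
#' tie handling: patients are ranked by `(prediction, patient_id)` with
#' stable order, then split into `n_quantiles` bins whose sizes differ by at
#' most one. Each bin reports its mean predicted risk and the Kaplan-Meier
#' observed risk at the horizon with its Greenwood CI.
#'
#' @inheritParams calibration_in_the_large
#' @param n_quantiles Number of bins, `>= 1`; default 5 (quintiles).
#' @param ids Optional patient identifiers used only to break prediction
#'   ties reproducibly; defaults to input order.
#' @param min_bin Minimum patients per bin; fewer aborts. Default 20.
#' @return Data frame of class `af_quantile_calibration`: `bin`, `n`,
#'   `n_events`, `mean_predicted`, `km_observed`, `ci_lo`, `ci_hi`.
#'   `km_observed` is `NA` for a bin with no at-risk patients at the horizon.
#' @export
quantile_calibration <- function(predictions, times, events, horizon,
                                 n_quantiles = 5, ids = NULL,
                                 min_bin = 20) {
  n <- length(predictions)
  stopifnot(length(times) == n, length(events) == n, n_quantiles >= 1)
  if (anyNA(predictions))
    af_abort("predictions contain NA; restrict to evaluable patients",
             class = "af_error_validate")
  if (is.null(ids)) ids <- sprintf("row%09d", seq_len(n))
  if (n < n_quantiles * min_bin)
    af_abort(sprintf(
      "need at least %d patients for %d bins of >= %d",
      n_quantiles * min_bin, n_quantiles, min_bin),
      class = "af_error_validate")
  ord <- order(predictions, ids)
  base <- n %/% n_quantiles
  extra <- n %% n_quantiles
  sizes <- rep(base, n_quantiles) + (seq_len(n_quantiles) <= extra)
  bin_sorted <- rep(seq_len(n_quantiles), times = sizes)
  bin <- integer(n)
  bin[ord] <- bin_sorted

  rows <- lapply(seq_len(n_quantiles), function(b) {
    sel <- bin == b
    at_risk <- sum(times[sel] > 0) > 0
    if (!at_risk) {
      return(data.frame(bin = b, n = sum(sel), n_events = 0L,
                        mean_predicted = mean(predictions[sel]),
                        km_observed = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_))
    }
    km <- kaplan_meier(times[sel], events[sel])
    ci <- km_ci_at(km, horizon)
    obs <- suppressWarnings(observed_risk(km, horizon))
    data.frame(bin = b, n = sum(sel),
               n_events = sum(events[sel] == 1 & times[sel] <= horizon),
               mean_predicted = mean(predictions[sel]),
               km_observed = obs,
               ci_lo = 1 - ci$upper, ci_hi = 1 - ci$lower)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("af_quantile_calibration", "data.frame")
  out
}
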