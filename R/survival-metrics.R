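#' @title Survival metrics: Kaplan-Meier, horizon AUC, Cox fits
#'
#' @description
#' Observed risk at a horizon is estimated by the Kaplan-Meier product-limit
#' method; discrimination by a horizon-specific AUC (C-statistic) over
#' case/control sets defined at the horizon; treatment effects by Cox
#' proportional-hazards regression. All confidence intervals use the 1.96
#' normal multiplier.
#'
#' @name survival-metrics
NULL

#' Kaplan-Meier product-limit estimate
#'
#' Thin, validated wrapper around [survival::survfit()] returning a plain
#' step-function representation. At tied times events are processed before
#' censorings (the standard product-limit convention).
#'
#' @param times Follow-up times in days, `>= 0`.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Object of class `af_km`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `lower`, `upper` (log-scale Greenwood CI), `n`.
#' @export
kaplan_meier <- function(times, events) {
  if (!length(times)) af_abort("empty input", class = "af_error_validate")
  if (length(times) != length(events))
    af_abort("times and events must have equal length",
             class = "af_error_validate")
  if (any(is.na(times) | times < 0))
    af_abort("times must be present and >= 0", class = "af_error_validate")
  if (!all(events %in% c(0, 1)))
    af_abort("events must be 0/1", class = "af_error_validate")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log")
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv, lower = fit$lower, upper = fit$upper,
                 n = length(times)),
            class = "af_km")
}

# S(t) with the right-continuous step convention; S(0-)=1
km_survival_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1]
}

km_ci_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  list(lower = c(1, km$lower)[idx + 1], upper = c(1, km$upper)[idx + 1])
}

#' Observed risk at a horizon
#'
#' `1 - S(horizon)` from a Kaplan-Meier curve, with `S` right-continuous.
#' A horizon beyond the last observed time extrapolates the last step and
#' warns.
#'
#' @param km An `af_km` from [kaplan_meier()].
#' @param horizon Horizon in days, `>= 0`.
#' @return Observed risk in `[0, 1]`.
#' @export
observed_risk <- function(km, horizon) {
  stopifnot(inherits(km, "af_km"))
  if (horizon < 0) af_abort("horizon must be >= 0",
                            class = "af_error_validate")
  if (length(km$time) && horizon > max(km$time))
    warning("horizon beyond last observed time; carrying the last ",
            "Kaplan-Meier step forward")
  1 - km_survival_at(km, horizon)
}

# horizon status under the exclusion rule:
#  case    = event by the horizon
#  control = event-free with follow-up reaching the horizon
#  NA      = censored event-free before the horizon (excluded)
af_horizon_status <- function(times, events, horizon) {
  case <- events == 1 & times <= horizon
  control <- !case & times >= horizon
  status <- rep(NA, length(times))
  status[case] <- TRUE
  status[control] <- FALSE
  status
}

# fast DeLong placement values: V10 per case, V01 per control
af_delong_placements <- function(pred_case, pred_ctrl) {
  n1 <- length(pred_case); n0 <- length(pred_ctrl)
  cr <- rank(c(pred_case, pred_ctrl), ties.method = "average")
  v10 <- (cr[seq_len(n1)] - rank(pred_case, ties.method = "average")) / n0
  v01 <- 1 - (cr[n1 + seq_len(n0)] -
                rank(pred_ctrl, ties.method = "average")) / n1
  list(v10 = v10, v01 = v01)
}

#' Horizon-specific AUC (C-statistic) under censoring
#'
#' Discrimination of a risk prediction for events by a horizon. With
#' `method = "exclude"` (default), cases are patients with the event by the
#' horizon, controls are patients event-free with follow-up reaching the
#' horizon, and patients censored event-free before the horizon are
#' excluded; the AUC is the fraction of concordant case-control pairs with
#' ties counted one-half, and its CI uses the DeLong asymptotic variance.
#' Alongside the AUC the case/control summary is returned: `n0`/`n1` counts
#' and `p0`/`p1` mean predicted risks in each group.
#'
#' With `method = "ipcw"` each case is weighted by the inverse Kaplan-Meier
#' estimate of the censoring survival at its event time (controls share a
#' common weight, which cancels); the CI uses a weighted-placement
#' approximation.
#'
#' @param predictions Numeric risk predictions (any monotone score works;
#'   the AUC is rank-based).
#' @param times,events Follow-up in days and event indicators, aligned with
#'   `predictions`.
#' @param horizon Horizon in days.
#' @param method `"exclude"` or `"ipcw"`.
#' @return Object of class `af_auc`: `auc`, `ci_lo`, `ci_hi`, `n0`, `p0`,
#'   `n1`, `p1`, `n_excluded`, `method`.
#' @export
horizon_auc <- function(predictions, times, events, horizon,
                        method = c("exclude", "ipcw")) {
  method <- match.arg(method)
  n <- length(predictions)
  stopifnot(length(times) == n, length(events) == n)
  if (anyNA(predictions))
    af_abort("predictions contain NA; restrict to evaluable patients",
             class = "af_error_validate")
  status <- af_horizon_status(times, events, horizon)
  case <- which(status %in% TRUE)
  ctrl <- which(status %in% FALSE)
  n1 <- length(case); n0 <- length(ctrl)
  if (n1 == 0 || n0 == 0)
    af_abort(sprintf(
      "AUC undefined at horizon %s: %d cases, %d controls",
      format(horizon), n1, n0), class = "af_error_degenerate",
      n0 = n0, n1 = n1)
  pl <- af_delong_placements(predictions[case], predictions[ctrl])

  if (method == "exclude") {
    auc <- mean(pl$v10)
    var_auc <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  } else {
    cens_km <- kaplan_meier(times, 1 - events)
    g <- km_survival_at(cens_km, pmin(times[case], horizon) - 1e-9)
    if (any(g <= 0))
      af_abort("censoring survival zero at a case event time",
               class = "af_error_degenerate")
    w <- (1 / g) / sum(1 / g)
    auc <- sum(w * pl$v10)
    # weighted-placement approximation to the DeLong variance
    var_auc <- sum(w * (pl$v10 - auc)^2) * sum(w^2) +
      stats::var(pl$v01) / n0
    var_auc <- max(var_auc, 0)
  }
  se <- sqrt(var_auc)
  structure(list(auc = auc,
                 ci_lo = max(0, auc - 1.96 * se),
                 ci_hi = min(1, auc + 1.96 * se),
                 n0 = n0, p0 = mean(predictions[ctrl]),
                 n1 = n1, p1 = mean(predictions[case]),
                 n_excluded = sum(is.na(status)), method = method),
            class = "af_auc")
}

#' @export
print.af_auc <- function(x, ...) {
  cat(sprintf(
    "<af_auc> AUC %.4f (95%% CI %.4f to %.4f); N1=%d P1=%.4f N0=%d P0=%.4f [%s]\n",
    x$auc, x$ci_lo, x$ci_hi, x$n1, x$p1, x$n0, x$p0, x$method))
  invisible(x)
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' Compares two predictors of the same horizon outcome on the same patients
#' using the DeLong test for correlated ROC curves. Antisymmetric:
#' `compare_auc(a, b)` has the negated delta of `compare_auc(b, a)`.
#'
#' @param pred_a,pred_b Aligned numeric predictions for the identical
#'   patient set.
#' @inheritParams horizon_auc
#' @return List of class `af_auc_comparison`: `auc_a`, `auc_b`, `delta`,
#'   `se`, `z`, `p_value`, `n0`, `n1`.
#' @export
compare_auc <- function(pred_a, pred_b, times, events, horizon) {
  n <- length(pred_a)
  if (length(pred_b) != n || length(times) != n || length(events) != n)
    af_abort("paired comparison requires identical patient sets",
             class = "af_error_validate")
  if (anyNA(pred_a) || anyNA(pred_b))
    af_abort("paired comparison requires both predictors evaluable (no NA)",
             class = "af_error_validate")
  status <- af_horizon_status(times, events, horizon)
  case <- which(status %in% TRUE)
  ctrl <- which(status %in% FALSE)
  n1 <- length(case); n0 <- length(ctrl)
  if (n1 == 0 || n0 == 0)
    af_abort("AUC comparison undefined: empty case or control set",
             class = "af_error_degenerate")
  pa <- af_delong_placements(pred_a[case], pred_a[ctrl])
  pb <- af_delong_placements(pred_b[case], pred_b[ctrl])
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  delta <- auc_a - auc_b
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (var_delta <= .Machine$double.eps) {
    z <- 0; p <- if (abs(delta) < .Machine$double.eps) 1 else 0
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, delta = delta,
                 se = sqrt(max(var_delta, 0)), z = z, p_value = p,
                 n0 = n0, n1 = n1),
            class = "af_auc_comparison")
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximisation of the Cox partial likelihood via
#' [survival::coxph()], with Efron tie handling by default and a tight
#' convergence tolerance. Non-convergence and apparent complete separation
#' are flagged on the result rather than silently accepted.
#'
#' @param covariates Data frame or matrix of covariates, no missing values.
#' @param times,events Follow-up in days and event indicators.
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @return Object of class `af_coxfit`: `coefficients` (data frame with
#'   `term`, `beta`, `hr`, `se`, `ci_lo`, `ci_hi`, `z`, `p_value`),
#'   `loglik` (null and fitted log partial likelihood), `converged`,
#'   `separation`, `n`, `n_events`, `ties`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.data.frame(covariates)
  x[] <- lapply(x, as.numeric)
  if (anyNA(x))
    af_abort("covariates contain missing values; filter to complete cases",
             class = "af_error_validate")
  if (sum(events) == 0)
    af_abort("no events: Cox model not estimable",
             class = "af_error_degenerate")
  dat <- cbind(data.frame(.time = times, .event = events), x)
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separation <- any(grepl("infinite", warn)) | any(abs(beta) > 15)
  converged <- !any(grepl("did not converge|out of iterations", warn)) &&
    !separation
  coefs <- data.frame(term = names(beta), beta = unname(beta),
                      hr = exp(unname(beta)), se = unname(se),
                      ci_lo = exp(unname(beta) - 1.96 * unname(se)),
                      ci_hi = exp(unname(beta) + 1.96 * unname(se)),
                      z = unname(beta) / unname(se),
                      p_value = 2 * stats::pnorm(-abs(unname(beta) /
                                                        unname(se))),
                      stringsAsFactors = FALSE)
  if (separation)
    warning("cox_fit: apparent complete separation or non-convergence; ",
            "estimates flagged unreliable")
  structure(list(coefficients = coefs, loglik = fit$loglik,
                 converged = converged, separation = separation,
                 n = length(times), n_events = sum(events), ties = ties),
            class = "af_coxfit")
}

#' @export
print.af_coxfit <- function(x, ...) {
  cat(sprintf("<af_coxfit> n=%d, events=%d, ties=%s, converged=%s\n",
              x$n, x$n_events, x$ties, x$converged))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
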