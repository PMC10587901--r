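#' @title Validation pipeline
#'
#' @description
#' Orchestrates the external-validation analysis of a set of risk equations
#' on a cohort: missingness accounting, per-model per-horizon discrimination
#' and calibration, paired comparisons against the point scores, subgroup
#' analyses, complete-case re-analysis, and adjusted treatment-effect Cox
#' models. Metric failures are confined to their cell: a degenerate
#' endpoint or stratum is logged and reported as `NA`, never aborts the run.
#'
#' Patients are canonically ordered by `patient_id` on entry, so a permuted
#' input produces a byte-identical report. No value is ever imputed.
#'
#' @name validation-pipeline
NULL

# outcomes for one endpoint aligned to the patient table order
af_outcomes_for <- function(cohort, endpoint) {
  oc <- cohort$outcomes[cohort$outcomes$endpoint == endpoint, ]
  oc[match(cohort$patients$patient_id, oc$patient_id), ]
}

af_sort_cohort <- function(cohort) {
  ord <- order(cohort$patients$patient_id)
  cohort$patients <- cohort$patients[ord, , drop = FALSE]
  rownames(cohort$patients) <- NULL
  oc <- cohort$outcomes
  oc <- oc[order(oc$endpoint, oc$patient_id), , drop = FALSE]
  rownames(oc) <- NULL
  cohort$outcomes <- oc
  cohort
}

af_subset_cohort <- function(cohort, keep_ids) {
  cohort$patients <-
    cohort$patients[cohort$patients$patient_id %in% keep_ids, , drop = FALSE]
  cohort$outcomes <-
    cohort$outcomes[cohort$outcomes$patient_id %in% keep_ids, , drop = FALSE]
  rownames(cohort$patients) <- rownames(cohort$outcomes) <- NULL
  cohort
}

#' Missingness accounting
#'
#' Per-variable missing fractions, per-model not-evaluable fractions (for
#' the point scores, "evaluable" means complete), and the complete-case
#' count under every model and both point scores.
#'
#' @param cohort An `af_cohort`.
#' @param specs List of `af_model_spec` objects.
#' @return List of class `af_missingness`: `variables` (variable,
#'   n_missing, frac_missing), `models` (model_id, n_evaluable,
#'   n_not_evaluable, frac_not_evaluable), `complete_case_n`.
#' @export
assess_missingness <- function(cohort, specs) {
  stopifnot(inherits(cohort, "af_cohort"))
  if (inherits(specs, "af_model_spec")) specs <- list(specs)
  p <- cohort$patients
  n <- nrow(p)
  vars <- c("age", "sex", "ethnicity", af_numeric_fields()[-1],
            af_flag_fields())
  variables <- data.frame(
    variable = vars,
    n_missing = vapply(vars, function(v) sum(is.na(p[[v]])), integer(1)),
    stringsAsFactors = FALSE)
  variables$frac_missing <- variables$n_missing / n

  ev <- lapply(specs, function(s) linear_predictor(p, s)$evaluable)
  names(ev) <- vapply(specs, `[[`, "", "model_id")
  ev$chads_vasc <- chads_vasc(p)$complete
  ev$has_bled <- has_bled(p)$complete
  models <- data.frame(
    model_id = names(ev),
    n_evaluable = vapply(ev, sum, integer(1)),
    n_not_evaluable = vapply(ev, function(e) sum(!e), integer(1)),
    stringsAsFactors = FALSE)
  models$frac_not_evaluable <- models$n_not_evaluable / n
  rownames(models) <- NULL
  structure(list(variables = variables, models = models,
                 complete_case_n = sum(Reduce(`&`, ev))),
            class = "af_missingness")
}

#' Complete-case subset
#'
#' Pure filter to the patients evaluable under every model specification and
#' complete for both point scores; no imputation ever.
#'
#' @inheritParams assess_missingness
#' @return The filtered `af_cohort`.
#' @export
complete_case <- function(cohort, specs) {
  stopifnot(inherits(cohort, "af_cohort"))
  if (inherits(specs, "af_model_spec")) specs <- list(specs)
  p <- cohort$patients
  keep <- Reduce(`&`, lapply(specs,
                             function(s) linear_predictor(p, s)$evaluable))
  keep <- keep & chads_vasc(p)$complete & has_bled(p)$complete
  if (!any(keep))
    af_abort(paste0("complete-case subset is empty; a complete-case ",
                    "analysis is not advisable for this cohort"),
             class = "af_error_degenerate")
  af_subset_cohort(cohort, p$patient_id[keep])
}

af_note <- function(e) conditionMessage(e)

#' Per-model validation (discrimination and calibration)
#'
#' For every model and every configured horizon available in the model:
#' predictions on the evaluable patients, horizon AUC with its case/control
#' summary (N1/P1 = number and mean predicted risk of patients with the
#' event by the horizon; N0/P0 = the same for event-free patients with
#' follow-up reaching it), Kaplan-Meier observed risk, calibration-in-the-
#' large, and the quantile calibration table. Deterministic given cohort and
#' config; cells fail independently with a log entry.
#'
#' Risk columns (`avg_predicted`, `km`, `p0`, `p1`, and the quantile means)
#' are reported in percent.
#'
#' @param cohort An `af_cohort`.
#' @param specs List of `af_model_spec` objects (or a single one).
#' @param config An [`af_config`][validation_config].
#' @return Object of class `af_validation_report` with data frames
#'   `validation`, `calibration`, `quantiles`, and a character `log`.
#' @export
run_validation <- function(cohort, specs, config = validation_config()) {
  stopifnot(inherits(cohort, "af_cohort"), inherits(config, "af_config"))
  if (inherits(specs, "af_model_spec")) specs <- list(specs)
  cohort <- af_sort_cohort(cohort)
  log <- character(0)
  val_rows <- list(); cal_rows <- list(); q_rows <- list()

  for (spec in specs) {
    hz <- intersect(config$horizons, spec$horizons)
    if (!length(hz)) {
      log <- c(log, sprintf("%s: no configured horizon tabulated; skipped",
                            spec$model_id))
      next
    }
    lp <- linear_predictor(cohort$patients, spec)
    oc <- af_outcomes_for(cohort, spec$outcome)
    ev <- lp$evaluable
    if (sum(!ev))
      log <- c(log, sprintf("%s: %d patients not evaluable (excluded)",
                            spec$model_id, sum(!ev)))
    for (h in hz) {
      risk <- predicted_risk(lp$lp[ev], spec, h)
      tt <- oc$time_days[ev]; ee <- oc$event[ev]
      hd <- months_to_days(h, config$days_per_month)
      key <- sprintf("%s @%gm", spec$model_id, h)

      auc <- tryCatch(horizon_auc(risk, tt, ee, hd,
                                  method = config$auc_method),
                      af_error = function(e) e)
      km_obs <- tryCatch(
        suppressWarnings(observed_risk(kaplan_meier(tt, ee), hd)),
        af_error = function(e) e)
      cal <- tryCatch(calibration_in_the_large(risk, tt, ee, hd),
                      af_error = function(e) e)
      qc <- tryCatch(quantile_calibration(risk, tt, ee, hd,
                                          n_quantiles = config$n_quantiles,
                                          ids = lp$patient_id[ev],
                                          min_bin = config$min_bin),
                     af_error = function(e) e)
      notes <- character(0)
      for (m in list(auc = auc, km = km_obs, cal = cal, quantiles = qc))
        if (inherits(m, "error")) notes <- c(notes, af_note(m))
      if (length(notes))
        log <- c(log, sprintf("%s: %s", key,
                              paste(unique(notes), collapse = "; ")))

      ok_auc <- !inherits(auc, "error")
      val_rows[[key]] <- data.frame(
        model = spec$model_id, outcome = spec$outcome, horizon = h,
        n = sum(ev),
        avg_predicted = 100 * mean(risk),
        km = if (inherits(km_obs, "error")) NA_real_ else 100 * km_obs,
        n0 = if (ok_auc) auc$n0 else NA_integer_,
        p0 = if (ok_auc) 100 * auc$p0 else NA_real_,
        n1 = if (ok_auc) auc$n1 else NA_integer_,
        p1 = if (ok_auc) 100 * auc$p1 else NA_real_,
        auc = if (ok_auc) auc$auc else NA_real_,
        auc_lo = if (ok_auc) auc$ci_lo else NA_real_,
        auc_hi = if (ok_auc) auc$ci_hi else NA_real_,
        stringsAsFactors = FALSE)
      if (!inherits(cal, "error")) {
        cal_rows[[key]] <- data.frame(
          model = spec$model_id, outcome = spec$outcome, horizon = h,
          n = cal$n, n_status = cal$n_status,
          mean_predicted = cal$mean_predicted,
          km_observed = cal$km_observed,
          intercept = cal$intercept, intercept_se = cal$intercept_se,
          slope = cal$slope, slope_se = cal$slope_se,
          n_clipped = cal$n_clipped, stringsAsFactors = FALSE)
      }
      if (!inherits(qc, "error")) {
        q_rows[[key]] <- cbind(
          data.frame(model = spec$model_id, outcome = spec$outcome,
                     horizon = h, stringsAsFactors = FALSE),
          as.data.frame(qc))
      }
    }
  }
  bindr <- function(x) {
    out <- do.call(rbind, unname(x))
    if (is.null(out)) out <- data.frame()
    rownames(out) <- NULL
    out
  }
  structure(list(validation = bindr(val_rows), calibration = bindr(cal_rows),
                 quantiles = bindr(q_rows), log = log),
            class = "af_validation_report")
}

#' @export
print.af_validation_report <- function(x, ...) {
  cat("<af_validation_report>\n")
  if (nrow(x$validation)) {
    df <- x$validation
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) round(v, 4))
    print(df, row.names = FALSE)
  }
  if (length(x$log)) cat("log:\n", paste(" -", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Paired AUC comparisons against the point scores
#'
#' For every model and horizon, compares the model's predicted risk with the
#' relevant comparator score — CHA2DS2-VASc for death and stroke, HAS-BLED
#' for major bleeding, the integer score used directly as the ranking
#' variable — with the DeLong paired test on the intersection of patients
#' evaluable under the model and complete for the score.
#'
#' @inheritParams run_validation
#' @return Object of class `af_validation_report` carrying a `comparisons`
#'   data frame and a `log`.
#' @export
run_comparisons <- function(cohort, specs, config = validation_config()) {
  stopifnot(inherits(cohort, "af_cohort"), inherits(config, "af_config"))
  if (inherits(specs, "af_model_spec")) specs <- list(specs)
  cohort <- af_sort_cohort(cohort)
  chads <- chads_vasc(cohort$patients)
  hasb <- has_bled(cohort$patients)
  log <- character(0)
  rows <- list()
  for (spec in specs) {
    comp <- if (spec$outcome == "major_bleed") hasb else chads
    comp_name <- attr(comp, "score_name")
    lp <- linear_predictor(cohort$patients, spec)
    oc <- af_outcomes_for(cohort, spec$outcome)
    shared <- lp$evaluable & comp$complete
    for (h in intersect(config$horizons, spec$horizons)) {
      key <- sprintf("%s vs %s @%gm", spec$model_id, comp_name, h)
      if (!any(shared)) {
        log <- c(log, sprintf("%s: no shared evaluable patients", key))
        next
      }
      risk <- predicted_risk(lp$lp[shared], spec, h)
      res <- tryCatch(
        compare_auc(risk, as.numeric(comp$score[shared]),
                    oc$time_days[shared], oc$event[shared],
                    months_to_days(h, config$days_per_month)),
        af_error = function(e) e)
      if (inherits(res, "error")) {
        log <- c(log, sprintf("%s: %s", key, af_note(res)))
        next
      }
      rows[[key]] <- data.frame(
        model = spec$model_id, comparator = comp_name,
        outcome = spec$outcome, horizon = h, n = sum(shared),
        auc_model = res$auc_a, auc_comparator = res$auc_b,
        delta = res$delta, p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, unname(rows))
  if (is.null(comparisons)) comparisons <- data.frame()
  rownames(comparisons) <- NULL
  structure(list(comparisons = comparisons, log = log),
            class = "af_validation_report")
}

#' Subgroup analyses
#'
#' Re-runs the per-model validation within each stratum of the configured
#' subgroup variables: anticoagulation at diagnosis (`oac`), stroke risk
#' strata from CHA2DS2-VASc ([stroke_risk_stratum()]), and bleeding strata
#' from the modified HAS-BLED ([bleed_risk_stratum()], restricted to
#' patients with a complete score). Strata smaller than
#' `config$min_stratum` are skipped with a log entry.
#'
#' @inheritParams run_validation
#' @return Object of class `af_validation_report` with a `subgroups` data
#'   frame (subgroup, level, then the validation columns) and a `log`.
#' @export
run_subgroups <- function(cohort, specs, config = validation_config()) {
  stopifnot(inherits(cohort, "af_cohort"), inherits(config, "af_config"))
  if (inherits(specs, "af_model_spec")) specs <- list(specs)
  cohort <- af_sort_cohort(cohort)
  p <- cohort$patients
  chads <- chads_vasc(p)
  hasb <- has_bled(p)
  strata <- list()
  if ("oac" %in% config$subgroups) {
    strata$oac <- factor(ifelse(p$oac %in% TRUE, "oac", "no_oac"),
                         levels = c("no_oac", "oac"))
    strata$oac[is.na(p$oac)] <- NA
  }
  if ("stroke_stratum" %in% config$subgroups) {
    s <- rep(NA_integer_, nrow(p))
    s[chads$complete] <- chads$score[chads$complete]
    strata$stroke_stratum <- stroke_risk_stratum(s)
  }
  if ("bleed_stratum" %in% config$subgroups) {
    s <- rep(NA_integer_, nrow(p))
    s[hasb$complete] <- hasb$score[hasb$complete]
    strata$bleed_stratum <- suppressMessages(bleed_risk_stratum(s))
  }
  log <- character(0)
  rows <- list()
  for (sg in names(strata)) {
    f <- strata[[sg]]
    for (lev in levels(f)) {
      sel <- !is.na(f) & f == lev
      if (sum(sel) < config$min_stratum) {
        log <- c(log, sprintf(
          "subgroup %s=%s: %d patients < %d minimum; skipped",
          sg, lev, sum(sel), config$min_stratum))
        next
      }
      sub <- af_subset_cohort(cohort, p$patient_id[sel])
      rep_sub <- run_validation(sub, specs, config)
      log <- c(log, sprintf("subgroup %s=%s: %s", sg, lev, rep_sub$log))
      if (nrow(rep_sub$validation)) {
        rows[[paste(sg, lev)]] <- cbind(
          data.frame(subgroup = sg, level = lev, stringsAsFactors = FALSE),
          rep_sub$validation)
      }
    }
  }
  subgroups <- do.call(rbind, unname(rows))
  if (is.null(subgroups)) subgroups <- data.frame()
  rownames(subgroups) <- NULL
  structure(list(subgroups = subgroups, log = log),
            class = "af_validation_report")
}

#' Adjusted treatment effect of anticoagulation
#'
#' One Cox model per endpoint: anticoagulation at diagnosis (`oac`) plus all
#' transformed covariates of that endpoint's risk-model specification
#' (conventionally the 2021-generation variable set), fitted on patients
#' with complete covariates. Returns the adjusted hazard ratio of `oac` per
#' endpoint.
#'
#' @param cohort An `af_cohort`.
#' @param specs List of `af_model_spec`, one per endpoint, defining the
#'   adjustment variables.
#' @return Data frame of class `af_treatment_effect`: `outcome`, `model`,
#'   `n`, `n_events`, `ahr`, `ci_lo`, `ci_hi`, `p_value`, `note`.
#' @export
treatment_effect <- function(cohort, specs) {
  stopifnot(inherits(cohort, "af_cohort"))
  if (inherits(specs, "af_model_spec")) specs <- list(specs)
  cohort <- af_sort_cohort(cohort)
  rows <- lapply(specs, function(spec) {
    p <- cohort$patients
    oc <- af_outcomes_for(cohort, spec$outcome)
    x <- data.frame(oac = as.numeric(p$oac))
    for (tm in spec$terms) {
      if (tm$covariate == "oac") next
      nm <- tm$covariate
      if (tm$transform$type != "linear")
        nm <- paste(nm, tm$transform$type, sep = "_")
      x[[nm]] <- af_apply_transform(af_covariate_values(p, tm$covariate),
                                    tm, p$patient_id)
    }
    keep <- stats::complete.cases(x)
    base <- data.frame(outcome = spec$outcome, model = spec$model_id,
                       n = sum(keep), stringsAsFactors = FALSE)
    fit <- tryCatch(
      cox_fit(x[keep, , drop = FALSE], oc$time_days[keep],
              oc$event[keep]),
      af_error = function(e) e)
    if (inherits(fit, "error")) {
      return(cbind(base, data.frame(n_events = sum(oc$event[keep]),
                                    ahr = NA_real_, ci_lo = NA_real_,
                                    ci_hi = NA_real_, p_value = NA_real_,
                                    note = af_note(fit))))
    }
    arm_events <- tapply(oc$event[keep], x$oac[keep], sum)
    note <- ""
    if (any(arm_events == 0) || !fit$converged)
      note <- "non-estimable or unreliable: zero events in an arm or no convergence"
    co <- fit$coefficients[fit$coefficients$term == "oac", ]
    cbind(base, data.frame(n_events = fit$n_events, ahr = co$hr,
                           ci_lo = co$ci_lo, ci_hi = co$ci_hi,
                           p_value = co$p_value, note = note,
                           stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("af_treatment_effect", "data.frame")
  out
}

#' Run the full validation study
#'
#' Missingness accounting, per-model validation, paired comparisons with the
#' point scores, subgroup analyses, complete-case re-analysis, and (when
#' `treatment_specs` is supplied) adjusted treatment effects — assembled
#' into one report ready for [write_report()].
#'
#' @inheritParams run_validation
#' @param treatment_specs Optional list of `af_model_spec` defining the
#'   per-endpoint adjustment sets for [treatment_effect()].
#' @return Object of class `af_validation_report` with components
#'   `validation`, `calibration`, `quantiles`, `comparisons`, `subgroups`,
#'   `missingness`, `complete_case`, `treatment`, `log`.
#' @export
run_study <- function(cohort, specs, config = validation_config(),
                      treatment_specs = NULL) {
  stopifnot(inherits(cohort, "af_cohort"))
  if (inherits(specs, "af_model_spec")) specs <- list(specs)
  cohort <- af_sort_cohort(cohort)
  miss <- assess_missingness(cohort, specs)
  main <- run_validation(cohort, specs, config)
  comp <- run_comparisons(cohort, specs, config)
  sub <- run_subgroups(cohort, specs, config)
  cc <- tryCatch({
    cc_cohort <- complete_case(cohort, specs)
    cc_rep <- run_validation(cc_cohort, specs, config)
    cc_rep$validation
  }, af_error = function(e) {
    main$log <- c(main$log, sprintf("complete-case: %s", af_note(e)))
    data.frame()
  })
  trt <- if (!is.null(treatment_specs))
    treatment_effect(cohort, treatment_specs) else data.frame()
  structure(list(validation = main$validation,
                 calibration = main$calibration,
                 quantiles = main$quantiles,
                 comparisons = comp$comparisons,
                 subgroups = sub$subgroups,
                 missingness = miss,
                 complete_case = cc,
                 treatment = trt,
                 log = c(main$log, comp$log, sub$log)),
            class = "af_validation_report")
}

# fixed-format CSV writer: 6-decimal numerics, empty string for NA,
# deterministic bytes
af_write_table <- function(df, path) {
  fmt <- function(v) {
    if (is.numeric(v) && !is.integer(v)) {
      whole <- v[!is.na(v)]
      out <- if (length(whole) && all(whole == round(whole)))
        sprintf("%.0f", v) else sprintf("%.6f", v)
    } else {
      out <- as.character(v)
    }
    out[is.na(v)] <- ""
    out
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  lines <- c(paste(names(df), collapse = ","),
             apply(cells, 1, paste, collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a validation report to delimited files
#'
#' Emits deterministic CSV tables (`validation.csv` mirroring the
#' predicted-vs-KM layout with columns
#' `model,outcome,horizon,n,avg_predicted,km,n0,p0,n1,p1,auc,auc_lo,auc_hi`,
#' plus comparison, calibration summary/quantile, missingness,
#' complete-case and treatment-effect tables as present) and a plain-text
#' run log. Numeric cells use six decimals; empty components are omitted
#' and logged. Round-trips through [read_report()] without loss at that
#' precision.
#'
#' @param report An `af_validation_report`.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "af_validation_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log <- report$log %||% character(0)
  emit <- function(df, name) {
    if (is.null(df) || !nrow(df)) {
      log <<- c(log, sprintf("%s: empty; file omitted", name))
      return()
    }
    path <- file.path(out_dir, name)
    af_write_table(df, path)
    written <<- c(written, path)
  }
  qt <- report$quantiles
  if (!is.null(qt) && nrow(qt)) names(qt)[names(qt) == "bin"] <- "quantile"
  emit(report$validation, "validation.csv")
  emit(report$comparisons, "comparisons.csv")
  emit(report$calibration, "calibration_summary.csv")
  emit(qt, "calibration_quantiles.csv")
  emit(report$subgroups, "subgroups.csv")
  if (!is.null(report$missingness)) {
    emit(report$missingness$variables, "missingness_variables.csv")
    emit(report$missingness$models, "missingness_models.csv")
  }
  emit(report$complete_case, "complete_case.csv")
  emit(report$treatment, "treatment_effect.csv")
  log_path <- file.path(out_dir, "run_log.txt")
  con <- file(log_path, open = "wb")
  writeLines(log, con, sep = "\n", useBytes = TRUE)
  close(con)
  written <- c(written, log_path)
  invisible(written)
}

#' Read back a written validation report
#'
#' @param out_dir Directory written by [write_report()].
#' @return Named list of data frames, one per table present.
#' @export
read_report <- function(out_dir) {
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  out <- lapply(files, utils::read.csv, stringsAsFactors = FALSE)
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}
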