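# programmatic fixtures and independent oracles used across the suite

# a patient table with every field present; override any column by name
make_patients <- function(n = 1, ...) {
  p <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = rep(70, n), sex = rep("male", n), ethnicity = rep("white", n),
    pulse = rep(80, n), sbp = rep(130, n), dbp = rep(80, n),
    weight = rep(80, n), height = rep(1.70, n),
    alcohol_units_per_week = rep(2, n),
    stringsAsFactors = FALSE)
  for (f in afvalidate:::af_flag_fields()) p[[f]] <- rep(FALSE, n)
  args <- list(...)
  for (nm in names(args)) p[[nm]] <- rep(args[[nm]], length.out = n)
  p
}

# write a cohort CSV fixture; flags as 1/0/blank
write_cohort_fixture <- function(path, patients, outcomes = NULL) {
  if (is.null(outcomes)) {
    for (ep in c("death", "stroke_se", "major_bleed")) {
      patients[[paste0("time_", ep)]] <- 365
      patients[[paste0("event_", ep)]] <- 0
    }
  }
  flags <- intersect(afvalidate:::af_flag_fields(), names(patients))
  patients[flags] <- lapply(patients[flags], function(x)
    ifelse(is.na(x), "", ifelse(x, "1", "0")))
  utils::write.csv(patients, path, row.names = FALSE, na = "",
                   quote = FALSE)
  path
}

# a tiny linear model spec: one age term, configurable
make_age_spec <- function(beta = 0.05, center = 70, s0 = c("12" = 0.9),
                          outcome = "death",
                          model_id = "fixture_age_model") {
  new_model_spec(
    model_id = model_id, outcome = outcome,
    horizons = as.numeric(names(s0)),
    terms = list(list(covariate = "age",
                      transform = list(type = "linear"), beta = beta)),
    centering = c(age = center), baseline_survival = s0)
}

# --- independent score oracles: per-record loops over a component table ---

oracle_chads <- function(row) {
  pts <- 0
  if (isTRUE(row$chf)) pts <- pts + 1
  if (isTRUE(row$hypertension)) pts <- pts + 1
  if (!is.na(row$age) && row$age >= 75) pts <- pts + 2
  else if (!is.na(row$age) && row$age >= 65) pts <- pts + 1
  if (isTRUE(row$diabetes)) pts <- pts + 1
  if (isTRUE(row$prior_stroke_tia)) pts <- pts + 2
  if (isTRUE(row$vascular_disease)) pts <- pts + 1
  if (identical(row$sex, "female")) pts <- pts + 1
  pts
}

oracle_hasbled <- function(row, include_labile_inr = FALSE) {
  pts <- 0
  htn <- if (!is.na(row$sbp)) row$sbp > 160 else isTRUE(row$hypertension)
  if (isTRUE(htn)) pts <- pts + 1
  if (isTRUE(row$abnormal_renal_function)) pts <- pts + 1
  if (isTRUE(row$abnormal_liver_function)) pts <- pts + 1
  if (isTRUE(row$prior_stroke_tia)) pts <- pts + 1
  if (isTRUE(row$bleeding_history)) pts <- pts + 1
  if (!is.na(row$age) && row$age > 65) pts <- pts + 1
  if (isTRUE(row$antiplatelet_or_nsaid)) pts <- pts + 1
  if (!is.na(row$alcohol_units_per_week) &&
      row$alcohol_units_per_week > 8) pts <- pts + 1
  if (include_labile_inr && isTRUE(row$labile_inr)) pts <- pts + 1
  pts
}

# brute-force all-pairs concordance with ties counted one half
oracle_auc_pairs <- function(pred_case, pred_ctrl) {
  tot <- 0
  for (x1 in pred_case) {
    for (x0 in pred_ctrl) {
      tot <- tot + (x1 > x0) + 0.5 * (x1 == x0)
    }
  }
  tot / (length(pred_case) * length(pred_ctrl))
}

# Cox partial log-likelihood (Breslow; equals Efron when times are unique)
oracle_cox_loglik <- function(beta, x, times, events) {
  lp <- as.matrix(x) %*% beta
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + lp[i] - log(sum(exp(lp[risk])))
  }
  as.numeric(ll)
}
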