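test_that("CHA2DS2-VASc matches hand-summed examples and flags incompleteness", {
  # all-negative 40-year-old male scores 0
  expect_equal(chads_vasc(make_patients(age = 40))$score, 0L)
  # female, 76, hypertensive, diabetic: 2 (age) + 1 + 1 + 1 (sex) = 5
  p <- make_patients(age = 76, sex = "female", hypertension = TRUE,
                     diabetes = TRUE)
  expect_equal(chads_vasc(p)$score, 5L)
  # male, 68, vascular disease only: 1 (age band) + 1 = 2
  p <- make_patients(age = 68, vascular_disease = TRUE)
  expect_equal(chads_vasc(p)$score, 2L)

  # a missing history flag scores 0 but marks the result incomplete
  p <- make_patients(age = 76, sex = "female", hypertension = NA)
  r <- chads_vasc(p)
  expect_equal(r$score, 3L)
  expect_false(r$complete)
  # missing age or sex: score undefined
  p <- make_patients(); p$age <- NA_real_
  r <- chads_vasc(p)
  expect_true(is.na(r$score))
  expect_false(r$complete)
})

test_that("HAS-BLED matches hand-summed examples and the SBP operationalisation", {
  expect_equal(has_bled(make_patients(age = 50))$score, 0L)
  # 70-year-old, bleeding history, abnormal renal function, 10 units/week:
  # age 1 + bleed 1 + renal 1 + alcohol 1 = 4
  p <- make_patients(age = 70, bleeding_history = TRUE,
                     abnormal_renal_function = TRUE,
                     alcohol_units_per_week = 10)
  expect_equal(has_bled(p)$score, 4L)

  # uncontrolled hypertension is SBP-driven when SBP is recorded
  p <- make_patients(age = 50, sbp = 170, hypertension = FALSE)
  expect_equal(has_bled(p)$score, 1L)
  # and falls back to the history flag when SBP is absent
  p <- make_patients(age = 50, hypertension = TRUE)
  p$sbp <- NA_real_
  expect_equal(has_bled(p)$score, 1L)
})

test_that("exhaustive enumeration bounds the scores: modified HAS-BLED tops out at 8", {
  grid <- expand.grid(hypertension = c(FALSE, TRUE),
                      abnormal_renal_function = c(FALSE, TRUE),
                      abnormal_liver_function = c(FALSE, TRUE),
                      prior_stroke_tia = c(FALSE, TRUE),
                      bleeding_history = c(FALSE, TRUE),
                      old = c(FALSE, TRUE),
                      antiplatelet_or_nsaid = c(FALSE, TRUE),
                      drinker = c(FALSE, TRUE),
                      labile_inr = c(FALSE, TRUE))
  p <- make_patients(nrow(grid))
  for (f in setdiff(names(grid), c("old", "drinker"))) p[[f]] <- grid[[f]]
  p$age <- ifelse(grid$old, 80, 50)
  p$alcohol_units_per_week <- ifelse(grid$drinker, 20, 2)
  p$sbp <- ifelse(p$hypertension, 170, 120)

  expect_equal(max(has_bled(p)$score), 8L)
  expect_equal(max(has_bled(p, include_labile_inr = TRUE)$score), 9L)
  expect_equal(min(has_bled(p)$score), 0L)
})

test_that("vectorised scores equal independent per-record summation", {
  set.seed(101)
  n <- 10000
  p <- make_patients(n,
    age = round(runif(n, 18, 100)),
    sex = sample(c("female", "male"), n, TRUE),
    sbp = round(runif(n, 90, 200)),
    alcohol_units_per_week = round(runif(n, 0, 30)))
  for (f in c("chf", "hypertension", "diabetes", "prior_stroke_tia",
              "vascular_disease", "bleeding_history",
              "abnormal_renal_function", "abnormal_liver_function",
              "antiplatelet_or_nsaid", "labile_inr"))
    p[[f]] <- sample(c(TRUE, FALSE), n, TRUE)

  cv <- chads_vasc(p)$score
  hb <- has_bled(p)$score
  hb_full <- has_bled(p, include_labile_inr = TRUE)$score
  for (i in sample(n, 400)) {
    expect_identical(cv[i], as.integer(oracle_chads(p[i, ])))
    expect_identical(hb[i], as.integer(oracle_hasbled(p[i, ])))
    expect_identical(hb_full[i], as.integer(oracle_hasbled(p[i, ], TRUE)))
  }
  expect_true(all(cv >= 0 & cv <= 9))
  expect_true(all(hb >= 0 & hb <= 8))
})

test_that("risk strata use the documented boundaries", {
  expect_equal(as.character(stroke_risk_stratum(c(0, 1, 4))),
               c("low", "moderate", "high"))
  expect_error(stroke_risk_stratum(10), class = "af_error_validate")

  expect_equal(as.character(suppressMessages(bleed_risk_stratum(c(1, 3)))),
               c("lower", "higher"))
  # the score-2 boundary is assigned to 'higher' with an explicit note
  expect_message(res <- bleed_risk_stratum(2), "assigned to 'higher'")
  expect_equal(as.character(res), "higher")
  expect_error(bleed_risk_stratum(-1), class = "af_error_validate")
})

test_that("linear predictor is the centered coefficient sum, never imputed", {
  # zero betas give lp = 0 for any record
  spec0 <- make_age_spec(beta = 0)
  expect_equal(linear_predictor(make_patients(age = 93), spec0)$lp, 0)

  # single age term, beta 0.05 centered at 70: age 80 gives 0.5
  spec <- make_age_spec(beta = 0.05, center = 70)
  expect_equal(linear_predictor(make_patients(age = 80), spec)$lp, 0.5)

  # a missing required covariate makes the patient not-evaluable
  spec_pulse <- new_model_spec(
    "m", "death", 12,
    list(list(covariate = "pulse", transform = list(type = "linear"),
              beta = 0.01)),
    "precentered", c("12" = 0.9))
  p <- make_patients(); p$pulse <- NA_real_
  lp <- linear_predictor(p, spec_pulse)
  expect_false(lp$evaluable)
  expect_true(is.na(lp$lp))

  # log-transform domain violations name the patient and term
  spec_log <- new_model_spec(
    "m", "death", 12,
    list(list(covariate = "weight", transform = list(type = "log"),
              beta = 1)),
    "precentered", c("12" = 0.9))
  p <- make_patients(); p$weight <- -2
  expect_error(linear_predictor(p, spec_log), "weight.*P001",
               class = "af_error_domain")
})

test_that("predicted risk follows the Cox survival transform", {
  spec <- make_age_spec(s0 = c("12" = 0.90))
  expect_equal(predicted_risk(0, spec, 12), 0.10)
  expect_equal(predicted_risk(log(2), spec, 12), 1 - 0.9^2)
  spec1 <- make_age_spec(s0 = c("12" = 1.0))
  expect_equal(predicted_risk(c(-3, 0, 5), spec1, 12), c(0, 0, 0))
  expect_error(predicted_risk(0, spec, 24), class = "af_error_spec")

  # strictly increasing in lp; non-decreasing in horizon
  spec2 <- make_age_spec(s0 = c("1" = 0.99, "12" = 0.90, "24" = 0.80))
  lp <- seq(-4, 4, length.out = 200)
  r12 <- predicted_risk(lp, spec2, 12)
  expect_true(all(diff(r12) > 0))
  expect_true(all(predicted_risk(lp, spec2, 1) <= r12))
  expect_true(all(r12 <= predicted_risk(lp, spec2, 24)))
})

test_that("with all betas zero the mean predicted risk equals 1 - S0 exactly", {
  cfg <- sim_config(n = 50, seed = 5)
  p <- generate_covariates(cfg)
  spec0 <- new_model_spec(
    "null_model", "death", c(1, 12),
    list(list(covariate = "age", transform = list(type = "linear"),
              beta = 0)),
    "precentered", c("1" = 0.995, "12" = 0.93))
  lp <- linear_predictor(p, spec0)
  expect_equal(mean(predicted_risk(lp$lp, spec0, 12)), 1 - 0.93)
  expect_equal(mean(predicted_risk(lp$lp, spec0, 1)), 1 - 0.995)
})

test_that("batch scoring emits one row per patient, model, and horizon", {
  cfg <- sim_config(n = 30, seed = 9)
  p <- generate_covariates(cfg)
  specs <- lapply(c("death", "stroke_se"), true_model_spec, config = cfg)
  out <- score_cohort(p, specs, horizons = c(1, 12))
  expect_equal(nrow(out), 30 * 2 * 2)
  expect_true(all(out$risk >= 0 & out$risk < 1))
  expect_true(all(out$evaluable))
})
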