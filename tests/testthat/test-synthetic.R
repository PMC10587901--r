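# one large cohort shared by the Monte-Carlo checks in this file
cfg_big <- sim_config(n = 100000, seed = 1)
pats_big <- generate_covariates(cfg_big)

test_that("covariate marginals converge to the configured targets", {
  expect_lt(abs(mean(pats_big$sex == "female") - 0.467), 0.01)
  targets <- c(hypertension = 0.708, diabetes = 0.137,
               prior_stroke_tia = 0.107, bleeding_history = 0.068,
               oac = 0.506, dementia = 0.022)
  for (f in names(targets)) {
    p0 <- targets[[f]]
    se <- sqrt(p0 * (1 - p0) / nrow(pats_big))
    expect_lt(abs(mean(pats_big[[f]]) - p0), 3 * se + 1e-3)
  }
  expect_lt(abs(mean(pats_big$age) - 74.6), 1)   # truncation shifts slightly
  expect_true(all(pats_big$age >= 18))
  expect_true(all(pats_big$sbp > pats_big$dbp & pats_big$dbp > 0))
  expect_identical(pats_big$oac, pats_big$noac | pats_big$vka)
})

test_that("age-tilted flags keep their marginal but gain the age gradient", {
  old <- pats_big$age > 80
  expect_gt(mean(pats_big$dementia[old]), mean(pats_big$dementia[!old]))
  expect_lt(mean(pats_big$current_smoker[old]),
            mean(pats_big$current_smoker[!old]))
})

test_that("the generator is deterministic and honours degenerate configs", {
  cfg <- sim_config(n = 1500, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$outcomes, c2$outcomes)

  cfg0 <- sim_config(n = 200, seed = 3,
                     prevalences = setNames(
                       rep(0, 18), names(afvalidate:::af_default_prevalences())))
  p0 <- generate_covariates(cfg0)
  for (f in setdiff(afvalidate:::af_flag_fields(), c("oac", "noac", "vka")))
    expect_true(all(p0[[f]] == FALSE))

  expect_error(sim_config(n = 100, prevalences = c(chf = 1.2)),
               class = "af_error_config")
})

test_that("zero-coefficient exponential outcomes match the closed-form risk", {
  scale <- 3000
  eps <- list(death = list(shape = 1, scale_days = scale,
                           centering = numeric(0), terms = list()),
              stroke_se = list(shape = 1, scale_days = 1e8,
                               centering = numeric(0), terms = list()),
              major_bleed = list(shape = 1, scale_days = 1e8,
                                 centering = numeric(0), terms = list()))
  cfg <- sim_config(n = 20000, seed = 8, endpoints = eps,
                    dropout_rate = 1e-9, admin_days = 1e7)
  coh <- simulate_cohort(cfg)
  oc <- coh$outcomes[coh$outcomes$endpoint == "death", ]
  p_true <- 1 - exp(-365.25 / scale)
  p_emp <- mean(oc$time_days <= 365.25 & oc$event == 1)
  se <- sqrt(p_true * (1 - p_true) / nrow(oc))
  expect_lt(abs(p_emp - p_true), 2 * se + 1e-4)
})

test_that("zero hazard multiplier yields a fully censored endpoint", {
  cfg <- sim_config(n = 300, seed = 12)
  cfg$miscalibration[["major_bleed"]] <- 0
  coh <- simulate_cohort(cfg)
  ocb <- coh$outcomes[coh$outcomes$endpoint == "major_bleed", ]
  expect_true(all(ocb$event == 0))
})

test_that("death truncates stroke and bleeding follow-up", {
  cfg <- sim_config(n = 5000, seed = 21)
  coh <- simulate_cohort(cfg)
  ocd <- coh$outcomes[coh$outcomes$endpoint == "death", ]
  ocs <- coh$outcomes[coh$outcomes$endpoint == "stroke_se", ]
  expect_true(all(ocs$time_days <= ocd$time_days + 1e-9))
})

test_that("the simulator's true model is recovered by the Cox fitter", {
  cfg <- sim_config(n = 20000, seed = 33)
  coh <- simulate_cohort(cfg)
  p <- coh$patients
  oc <- coh$outcomes[coh$outcomes$endpoint == "stroke_se", ]
  oc <- oc[match(p$patient_id, oc$patient_id), ]
  x <- data.frame(age = p$age, female = as.numeric(p$sex == "female"),
                  prior_stroke_tia = as.numeric(p$prior_stroke_tia),
                  hypertension = as.numeric(p$hypertension),
                  diabetes = as.numeric(p$diabetes),
                  vascular_disease = as.numeric(p$vascular_disease),
                  oac = as.numeric(p$oac))
  fit <- cox_fit(x, oc$time_days, oc$event)
  truth <- c(age = 0.045, female = 0.15, prior_stroke_tia = 0.70,
             hypertension = 0.30, diabetes = 0.25,
             vascular_disease = 0.20, oac = log(0.71))
  co <- fit$coefficients
  for (nm in names(truth)) {
    row <- co[co$term == nm, ]
    expect_lt(abs(row$beta - truth[[nm]]), 4 * row$se)
  }
})

test_that("MCAR injection hits the configured rates and nothing else", {
  p <- pats_big
  rates <- c(pulse = 1, alcohol_units_per_week = 0.333)
  p2 <- inject_missingness(p, rates, seed = 5)
  expect_true(all(is.na(p2$pulse)))
  expect_lt(abs(mean(is.na(p2$alcohol_units_per_week)) - 0.333), 0.01)
  expect_identical(p2$age, p$age)

  # the HAS-BLED evaluable fraction drops by exactly the injected rate
  hb <- has_bled(p2)
  expect_lt(abs(mean(hb$complete) - (1 - 0.333)), 0.01)

  expect_identical(inject_missingness(p, numeric(0), seed = 1), p)
  expect_error(inject_missingness(p, c(pulse = 1.5)),
               class = "af_error_config")
  expect_error(inject_missingness(p, c(not_a_field = 0.5)),
               class = "af_error_config")
})

test_that("miscalibration injection rescales hazards but not the evaluated spec", {
  cfg <- sim_config(n = 4000, seed = 44)
  cfg2 <- inject_miscalibration(cfg, c(death = 2))
  expect_equal(cfg2$miscalibration[["death"]], 2)
  expect_error(inject_miscalibration(cfg, c(death = 0)),
               class = "af_error_config")
  expect_error(inject_miscalibration(cfg, c(nonsense = 2)),
               class = "af_error_config")

  spec <- true_model_spec(cfg, "death", horizons = 12)
  spec2 <- true_model_spec(cfg2, "death", horizons = 12)
  expect_identical(spec$baseline_survival, spec2$baseline_survival)

  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg2)
  ev1 <- sum(coh1$outcomes$event[coh1$outcomes$endpoint == "death"])
  ev2 <- sum(coh2$outcomes$event[coh2$outcomes$endpoint == "death"])
  expect_gt(ev2, ev1)
})
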