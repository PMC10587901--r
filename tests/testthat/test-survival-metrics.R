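test_that("Kaplan-Meier reproduces hand product-limit values and edge cases", {
  # no events: survival 1 everywhere, observed risk 0
  km0 <- kaplan_meier(c(5, 10, 15, 20, 25), rep(0, 5))
  expect_equal(observed_risk(km0, 20), 0)

  # worked example: times (2,3,3,5,8), events (1,1,0,1,0)
  # S(5) = (4/5)(3/4)(1/2) = 0.30
  km <- kaplan_meier(c(2, 3, 3, 5, 8), c(1, 1, 0, 1, 0))
  expect_equal(unname(afvalidate:::km_survival_at(km, 5)), 0.30)
  expect_equal(observed_risk(km, 5), 0.70)

  # certain event at t = 1
  km1 <- kaplan_meier(rep(1, 4), rep(1, 4))
  expect_equal(observed_risk(km1, 1), 1)

  # horizon beyond last observed time carries the last step with a warning
  expect_warning(r <- observed_risk(km, 100), "beyond last")
  expect_equal(r, 0.70)

  expect_error(kaplan_meier(numeric(0), numeric(0)),
               class = "af_error_validate")
  expect_error(kaplan_meier(c(-1, 2), c(1, 0)),
               class = "af_error_validate")
})

test_that("Kaplan-Meier equals the empirical survival when nothing is censored", {
  set.seed(20)
  for (i in 1:5) {
    tt <- sample(1:40, 30, replace = TRUE)
    km <- kaplan_meier(tt, rep(1, 30))
    for (h in c(5, 15, 35)) {
      expect_equal(unname(afvalidate:::km_survival_at(km, h)),
                   mean(tt > h))
    }
  }
})

test_that("horizon AUC equals brute-force pair counting and honours conventions", {
  # perfect separation
  r <- horizon_auc(c(0.9, 0.8, 0.1, 0.2), c(10, 20, 400, 400),
                   c(1, 1, 0, 0), horizon = 365)
  expect_equal(r$auc, 1)
  expect_equal(c(r$n1, r$n0), c(2, 2))

  # all-tied predictions give exactly one half
  r <- horizon_auc(rep(0.3, 10), c(rep(10, 4), rep(400, 6)),
                   c(rep(1, 4), rep(0, 6)), horizon = 365)
  expect_equal(r$auc, 0.5)

  # uncensored synthetic records against the double-loop oracle
  set.seed(7)
  n <- 50
  pred <- round(runif(n), 2)              # ties on purpose
  ev <- rbinom(n, 1, plogis(3 * (pred - 0.5)))
  tt <- ifelse(ev == 1, runif(n, 1, 300), 400)
  r <- horizon_auc(pred, tt, ev, horizon = 365)
  expect_equal(r$auc, oracle_auc_pairs(pred[ev == 1], pred[ev == 0]),
               tolerance = 1e-12)
  expect_equal(r$n1, sum(ev))
  expect_equal(r$p1, mean(pred[ev == 1]))
  expect_equal(r$p0, mean(pred[ev == 0]))
  expect_true(r$ci_lo <= r$auc && r$auc <= r$ci_hi)

  # censoring: early event-free censorings are excluded, and the oracle
  # applied to the included sets agrees
  tt2 <- tt; ev2 <- ev
  cens <- ev == 0 & seq_len(n) %% 3 == 0
  tt2[cens] <- runif(sum(cens), 1, 300)   # censored before the horizon
  r2 <- horizon_auc(pred, tt2, ev2, horizon = 365)
  expect_equal(r2$n_excluded, sum(cens))
  inc_case <- ev2 == 1 & tt2 <= 365
  inc_ctrl <- ev2 == 0 & tt2 >= 365
  expect_equal(r2$auc, oracle_auc_pairs(pred[inc_case], pred[inc_ctrl]),
               tolerance = 1e-12)
})

test_that("AUC is rank-based: invariant to monotone transforms, flipped by negation", {
  set.seed(8)
  pred <- runif(80)
  ev <- rbinom(80, 1, pred)
  tt <- ifelse(ev == 1, 100, 400)
  a <- horizon_auc(pred, tt, ev, 365)$auc
  expect_equal(horizon_auc(qlogis(pred), tt, ev, 365)$auc, a)
  expect_equal(horizon_auc(pred^3, tt, ev, 365)$auc, a)
  expect_equal(horizon_auc(-pred, tt, ev, 365)$auc, 1 - a)
})

test_that("horizon AUC agrees with an independent ROC implementation", {
  set.seed(12)
  pred <- runif(200)
  ev <- rbinom(200, 1, plogis(4 * (pred - 0.5)))
  tt <- ifelse(ev == 1, 50, 400)
  r <- horizon_auc(pred, tt, ev, 365)
  ref <- pROC::roc(ev, pred, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(r$ci_lo, ref_ci[1], tolerance = 1e-4)
  expect_equal(r$ci_hi, ref_ci[3], tolerance = 1e-4)
})

test_that("degenerate case/control sets raise a classed error, not NaN", {
  expect_error(horizon_auc(c(0.1, 0.2), c(400, 400), c(0, 0), 365),
               class = "af_error_degenerate")
  expect_error(horizon_auc(c(0.1, 0.2), c(10, 20), c(1, 1), 365),
               class = "af_error_degenerate")
})

test_that("IPCW AUC equals the exclusion AUC when nothing is censored early", {
  set.seed(13)
  pred <- runif(100)
  ev <- rbinom(100, 1, pred)
  tt <- ifelse(ev == 1, runif(100, 1, 300), 400)
  a <- horizon_auc(pred, tt, ev, 365, method = "exclude")
  b <- horizon_auc(pred, tt, ev, 365, method = "ipcw")
  expect_equal(b$auc, a$auc, tolerance = 1e-12)
})

test_that("paired AUC comparison is antisymmetric and detects real differences", {
  set.seed(30)
  n <- 200
  risk <- runif(n)
  ev <- rbinom(n, 1, risk)
  tt <- ifelse(ev == 1, 100, 400)
  noise <- runif(n)

  # identical predictors: delta 0, p = 1
  same <- compare_auc(risk, risk, tt, ev, 365)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)

  # antisymmetry
  ab <- compare_auc(risk, noise, tt, ev, 365)
  ba <- compare_auc(noise, risk, tt, ev, 365)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_value, ba$p_value)

  # informative vs random predictor: both the DeLong p-value and an
  # independent permutation test (random pairwise swaps under
  # exchangeability) reject at the 5% level
  expect_lt(ab$p_value, 0.05)
  case <- ev == 1
  fast_auc <- function(x) {
    r <- rank(x)
    (sum(r[case]) - sum(case) * (sum(case) + 1) / 2) /
      (sum(case) * sum(!case))
  }
  d_obs <- fast_auc(risk) - fast_auc(noise)
  set.seed(31)
  d_perm <- replicate(10000, {
    swap <- runif(n) < 0.5
    a <- ifelse(swap, noise, risk)
    b <- ifelse(swap, risk, noise)
    fast_auc(a) - fast_auc(b)
  })
  p_perm <- mean(abs(d_perm) >= abs(d_obs))
  expect_lt(p_perm, 0.05)

  # mismatched patient sets are refused
  expect_error(compare_auc(risk[-1], noise, tt, ev, 365),
               class = "af_error_validate")
})

test_that("Cox fitting recovers a known hazard ratio and matches a generic optimiser", {
  set.seed(40)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.001 * 2^x)
  ev <- as.integer(tt < 2000)
  tt <- pmin(tt, 2000)
  fit <- cox_fit(data.frame(group = x), tt, ev)
  hr <- fit$coefficients$hr[1]
  expect_true(hr > 1.85 && hr < 2.15)
  expect_true(fit$coefficients$ci_lo[1] < 2 & 2 < fit$coefficients$ci_hi[1])
  expect_true(fit$converged)
  # fitted log partial likelihood improves on the null
  expect_gte(fit$loglik[2], fit$loglik[1])

  # small fixture with unique event times: partial-likelihood optimum from
  # a generic optimiser agrees to 1e-4
  set.seed(41)
  m <- 60
  z <- rnorm(m)
  t2 <- rexp(m, 0.01 * exp(0.7 * z)) + runif(m, 0, 1e-4)
  e2 <- rep(1L, m)
  fit2 <- cox_fit(data.frame(z = z), t2, e2)
  opt <- optimize(function(b) -oracle_cox_loglik(b, cbind(z), t2, e2),
                  c(-3, 3), tol = 1e-10)
  expect_equal(fit2$coefficients$beta[1], opt$minimum, tolerance = 1e-4)

  expect_error(cox_fit(data.frame(z = z), t2, rep(0L, m)),
               class = "af_error_degenerate")
  expect_error(cox_fit(data.frame(z = c(NA, z[-1])), t2, e2),
               class = "af_error_validate")
})

test_that("Cox confidence intervals cover a null effect at the nominal rate", {
  set.seed(50)
  cover <- logical(100)
  for (i in 1:100) {
    x <- rbinom(1000, 1, 0.5)
    tt <- rexp(1000, 0.002)       # independent of x
    ev <- as.integer(tt < 1000)
    tt <- pmin(tt, 1000)
    fit <- cox_fit(data.frame(x = x), tt, ev)
    cover[i] <- fit$coefficients$ci_lo[1] < 1 & 1 < fit$coefficients$ci_hi[1]
  }
  expect_gte(mean(cover), 0.90)
})
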