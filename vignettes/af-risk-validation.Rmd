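---
title: "Validating multi-outcome risk equations in atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating multi-outcome risk equations in atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afvalidate)
```

## The problem

Patients with newly diagnosed non-valvular atrial fibrillation (AF) face
three competing concerns: death, ischaemic stroke or systemic embolism, and
— if anticoagulated to prevent the stroke — major bleeding. Guideline
practice scores stroke risk with CHA₂DS₂-VASc and bleeding risk with
HAS-BLED, both small integer point scores. Multi-outcome Cox risk equations
(the GARFIELD-AF 2017 and 2021 tools are the prominent examples) instead
predict absolute risks of all three endpoints from one covariate set.
Whether such equations transport to a new population is an empirical
question: discrimination and calibration must be re-measured on an external
cohort. `afvalidate` implements that external-validation workflow
end-to-end, together with a synthetic incident-AF cohort generator with
known ground truth, so the whole pipeline is testable without access to
licensed electronic-health-record data.

## The risk model

A risk equation is a transcription, never a re-fit. A coefficient file
(JSON, schema in `inst/extdata/model-spec-schema.json`) carries terms
$(x_j, t_j, \beta_j)$, centering metadata, and a baseline survival
$S_0(t)$ per horizon. The predicted risk of the event by horizon $t$ is

$$ r(x, t) = 1 - S_0(t)^{\exp(lp)}, \qquad
   lp = \sum_j \beta_j\,\{t_j(x_j) - t_j(\bar x_j)\}. $$

Supported transforms are linear, log, linear-spline (hinge) and threshold
indicators — enough to transcribe published age splines and category
cut-offs without guessing their form. The transform family is validated at
load time, as are $0 < S_0 \le 1$ and monotonicity of $S_0$ in the
horizon. The three files shipped under `inst/extdata/models/` are
*synthetic* stand-ins with plausible coefficients (published coefficient
supplements are licensed material); they exercise the format, not any
specific published tool.

Missing covariates are handled asymmetrically and deliberately so:

* **Risk equations never impute.** A patient missing any required
  covariate is *not evaluable* and is excluded from that model's
  validation, which is exactly what the pipeline's missingness accounting
  counts.
* **Point scores always compute.** A missing component contributes 0
  points and flips `complete = FALSE`, mirroring how such scores are used
  in primary-care records where history flags are often simply absent.

## Point-score conventions

The CHA₂DS₂-VASc weights (1/1/2/1/2/1/1/1) and the one-point HAS-BLED
components follow the original published definitions. Operationalisations
the source definitions leave open are configurable with documented
defaults: HAS-BLED "uncontrolled hypertension" is SBP > 160 mmHg when SBP
is recorded, else the hypertension-history flag; alcohol excess is > 8
units/week. Baseline records rarely carry an INR history, so the default
HAS-BLED variant drops the labile-INR component and its maximum attainable
score is 8 rather than 9 (`has_bled(..., include_labile_inr = TRUE)`
restores the full score). Stroke strata are low = 0, moderate = 1,
high ≥ 2. The customary bleeding split "HAS-BLED < 2 or > 2" never says
where 2 belongs; `bleed_risk_stratum()` assigns it to the higher stratum
and says so in a message — a documented convention, not an inference.

## Discrimination under censoring

The AUC of a risk prediction for "event by horizon $t$" needs a definition
of cases and controls under right censoring. The default (`"exclude"`)
is status-based: cases have the event by $t$, controls are event-free with
follow-up reaching $t$, and patients censored event-free before $t$ are
excluded; the AUC is the all-pairs concordance fraction with ties counted
one half. This reproduces the familiar reporting layout N1/P1 (count and
mean predicted risk of cases) and N0/P0 (the same for controls).
Status-based exclusion is not the only defensible choice, so an
inverse-probability-of-censoring-weighted variant (`"ipcw"`, Kaplan-Meier
censoring weights on cases) ships as a sensitivity option. Confidence
intervals use the DeLong asymptotic variance of the placement values, and
paired model-versus-score comparisons use the DeLong test for correlated
ROC curves on the *intersection* of patients evaluable under both
predictors — a paired test is meaningless on differing subject sets, so
disjoint sets are an error, not a silent union. Integer point scores enter
comparisons directly as ranking variables.

## Observed risk and calibration

Observed risk at a horizon is $1 - \hat S(t)$ from the Kaplan-Meier
product-limit estimator (`survival::survfit` underneath), with the
right-continuous step convention and events processed before censorings at
tied times. Greenwood log-scale intervals accompany every estimate.

Calibration is summarised two ways:

* **Calibration-in-the-large**: the intercept of a logistic recalibration
  of horizon status on an offset of $\mathrm{logit}(\hat r)$ (slope fixed
  at 1); the calibration slope comes from the un-offset fit. A positive
  intercept means the model underpredicts. Because dropping early-censored
  controls over-represents cases — enough to bias the intercept by roughly
  $-\log G(t)$, about +0.17 at 12 months under the default dropout rate,
  even for a perfect model — both regressions weight each retained patient
  by the inverse Kaplan-Meier censoring survival at its
  status-determination time. With no censoring before the horizon every
  weight is 1 and the fit is the plain offset-logistic recalibration.
  Predictions at exactly 0 or 1 are clipped to $[10^{-6}, 1-10^{-6}]$ and
  the clip count reported. A pseudo-observation (survival-scale) variant
  would be a reasonable alternative; it is out of scope and noted here.
* **Quantile calibration**: patients are ranked by
  (prediction, patient id) — a stable, reproducible tie-break — and split
  into `n_quantiles` bins (default 5, quintiles) whose sizes differ by at
  most one; each bin compares its mean predicted risk with its
  Kaplan-Meier observed risk at the horizon. Systematic underprediction
  that grows with predicted risk shows up as a widening gap in the upper
  quintiles, which is exactly the pattern the simulator's miscalibration
  multiplier reproduces.

## Pipeline semantics

`run_study()` chains missingness accounting, per-model validation, paired
score comparisons, subgroup analyses (anticoagulated versus not, stroke
strata, bleeding strata; strata under 50 patients are skipped with a log
entry), a complete-case re-analysis (patients evaluable under *every*
model and both scores — a pure filter, imputation is deliberately
unavailable), and adjusted treatment-effect Cox models (anticoagulation
plus each endpoint's risk-equation covariates; Efron ties; convergence
tolerance $10^{-9}$, 100 iterations; non-convergence and separation are
flagged, never silent). Cells fail independently: one degenerate endpoint
yields `NA` cells and a log line, not an aborted run.

Determinism is a contract: patients are canonically sorted by id on
pipeline entry, so permuting input rows produces byte-identical report
files (floating-point summation order would otherwise leak into the last
digits). Report CSVs are written with fixed six-decimal formatting for the
same reason.

## The synthetic cohort

The generator emulates a UK primary-care incident-AF population:

* **Covariates.** Age truncated-normal (mean 74.6, SD 12.2, ≥ 18); 46.7%
  female; flag prevalences matching a published baseline table of such a
  cohort (hypertension 70.8%, diabetes 13.7%, prior stroke/TIA 10.7%,
  bleeding history 6.8%, anticoagulated at diagnosis 50.6%, …);
  age-associated flags drawn through a mean-preserving logistic tilt
  (intercept re-solved against the sampled ages so marginals stay on
  target); vitals normal with physiologic clipping and diastolic pressure
  derived from systolic minus a pulse-pressure draw so `sbp > dbp > 0`
  always holds.
* **Outcomes.** Weibull proportional-hazards inversion per endpoint,
  $T = \mathrm{scale}\,(-\log U / m\,e^{lp})^{1/\mathrm{shape}}$, with
  default shape 1 and scales (3816, 6663, 7230 days) solved once so the
  simulated cohort's *marginal* 12-month Kaplan-Meier risks match the
  published cohort-level values (death 11.89%, stroke 8.29%, major bleed
  6.32%). Anticoagulation enters every true model at the adjusted hazard
  ratios reported for such a cohort (death 0.58, stroke 0.71, bleeding
  0.90). Dropout is exponential with median ≈ 4 years; administrative
  censoring at 22.6 years; death truncates stroke and bleeding follow-up
  (cause-specific censoring, not a competing-risks sub-distribution).
* **Known truth.** `true_model_spec()` returns the exact generating model
  as a coefficient file ($S_0(t) = e^{-(t/\mathrm{scale})^{\mathrm{shape}}}$),
  so validating it against its own simulation is a self-consistency check;
  `inject_miscalibration()` inflates the true hazards while leaving that
  spec untouched, producing controlled underprediction. Missingness is
  MCAR per variable (`cprd_like_missingness()` gives a realistic preset;
  the default is a clean cohort) — sufficient to test the accounting and
  complete-case logic, which is all it claims.

Three seeded streams (`seed`, `seed + 1`, `seed + 2` for covariates,
outcomes, missingness) make every stage independently reproducible.

What the simulator does **not** emulate — and hence what passing tests do
not demonstrate about real records: joint covariate structure beyond the
age tilt (no copulas), informative or structured missingness, coding and
linkage artefacts, practice-level clustering, and secular treatment
trends. External validation on real data remains a separate exercise; this
package guarantees the *machinery* is correct, not that any particular
tool is transportable.

## Numerical choices

* Horizons are quoted in months and converted at 30.4375 days/month
  (12 months = 365.25 days exactly); the constant is configurable.
* All 95% intervals use the 1.96 normal multiplier.
* AUC and comparison placements are computed by the rank-based DeLong
  identities (no $O(n_0 n_1)$ pair loops outside the test oracles).
* Degenerate inputs (no cases, no controls, single-status calibration,
  zero events) raise classed conditions (`af_error_degenerate`) that the
  pipeline converts to logged `NA` cells.

## Problem sizes in the test suite

Monte-Carlo checks use cohorts of 20,000 (self-consistency, parameter
recovery, discrimination ordering) and 100,000 (covariate marginals), with
tolerances set from binomial or asymptotic standard errors at those sizes;
the worked oracle examples (hand product-limit values, brute-force
concordance, enumeration of score components) are exact. Parameter
recovery for the anticoagulation effect is asserted on the mean log hazard
ratio across ten replicate cohorts with CI coverage in at least seven —
a single 95% interval misses its target for one seed in twenty by
construction, and the replicate design tests the estimator rather than the
luck of one draw.

## A worked self-consistency run

```{r, eval = FALSE}
cfg <- sim_config(n = 20000, seed = 1)
cohort <- simulate_cohort(cfg)
specs <- lapply(c("death", "stroke_se", "major_bleed"),
                function(ep) true_model_spec(cfg, ep))
report <- run_study(cohort, specs, validation_config(),
                    treatment_specs = specs)
report$validation
write_report(report, "report/")
```

Validating the generating model on its own simulation, the 12-month rows
show mean predicted risk within Monte-Carlo error of the Kaplan-Meier
observed risk, calibration intercepts near zero, and AUCs well above the
paired point-score comparators; doubling a true hazard with
`inject_miscalibration()` flips every quintile to observed-above-predicted
with the gap widest in the top quintile.
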