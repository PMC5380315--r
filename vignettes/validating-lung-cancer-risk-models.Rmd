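---
title: "Validating lung cancer screening risk models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating lung cancer screening risk models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcriskval)
```

## The problem

Lung cancer screening guidelines select candidates by age and cumulative
smoking exposure: at least 30 pack-years and, for former smokers, cessation
less than 15 years ago. Dichotomizing pack-years discards information —
smoking duration, intensity and time since quitting contribute separately to
risk, as do comorbidities and family history. Absolute-risk prediction
models use that information, and the question this package is built around
is how to *compare* such models, fairly and at scale, against each other and
against the pack-year criteria: calibration, discrimination, and — the part
that speaks to policy — clinical usefulness in decision-curve terms.

The package implements the full comparison pipeline for nine model
structures: the logistic PLCOm2012 model and a simplified (age + smoking)
variant; the Liverpool Lung Project (LLP) model, which multiplies an
age–sex baseline risk by covariate odds ratios, and its simplified variant;
the Bach model (annual lung-cancer and competing-death hazards composed over
one-year cycles); the Knoke lung-cancer death model (annual hazards, no
competing-death term); and three two-stage clonal expansion (TSCE)
biological carcinogenesis models (one incidence fit and two death fits).

Because the NLST and PLCO trial microdata are access-restricted, every stage
is exercised on synthetic cohorts that emulate the published marginal
structure of those populations. The package's tests therefore demonstrate
that the *machinery* is correct and that the *qualitative* published
comparison (risk models out-rank the pack-year criteria at matched selected
counts) reproduces under a declared generating model — they do not, and
cannot, re-derive the trials' numerical AUCs.

## Model payloads: published versus synthetic stand-ins

Coefficients live in versioned YAML files under `inst/extdata/models/`, one
per model; code carries structure only.

* `plcom2012.yaml` transcribes the published PLCOm2012 coefficient table
  (Tammemagi et al. 2013): a logistic model in age, race/ethnicity,
  education, BMI, COPD, personal and family cancer history, smoking status,
  duration, quit-years, and the reciprocal-power intensity transform
  `(cigs/10)^-1` (centred). This payload is exact.
* Every other payload is a **synthetic stand-in**, flagged by a
  `_synthetic.yaml` suffix and a `provenance: synthetic` field: the original
  publications' full coefficient sets (spline bases, baseline tables,
  per-gender TSCE rate constants) are not reproduced here. Stand-ins keep
  the published structure exactly — the quantity computed, the covariates,
  the composition rule — with constants calibrated to produce realistic
  absolute-risk magnitudes (heavy-smoker six-year incidence of a few
  percent; never-smoker hazards of order 10^-4/year).
* The LLP stand-ins were calibrated by *fitting the LLP structure* (age-band
  baseline × duration-category odds ratios) to a large synthetic development
  cohort, mirroring how the original case–control model was fitted to its
  development data. In the synthetic joint distribution, duration proxies
  quit-years and lifetime exposure (duration = age − start age − quit
  years), so the fitted duration gradient is steeper than the original
  publication's; this is a property of the declared generator, not of the
  real LLP.

Results obtained with the stand-in payloads characterize the pipeline, not
the original models' performance on trial data.

Two assumptions from the trial harmonization carry over as defaults:
asbestos exposure is taken as absent (it was unavailable in both trials and
affects under 5% of participants), and family-history onset age maps to
"late" (relative diagnosed after 60), since questionnaires recorded
occurrence only and most relatives' lung cancers occur after 60. Both are
per-subject overridable through the cohort table.

## The TSCE hazard engine

The two-stage clonal expansion model posits initiation of normal cells at
aggregate rate $\nu(t)$, clonal expansion of initiated cells (division rate
$\alpha$, death rate $\beta$), malignant transformation at rate $\mu$, and a
fixed lag from first malignant cell to detected cancer or death. Smoking
enters through dose–response factors $1 + c\,d^{\,p}$ on $\nu$, on the net
proliferation $\alpha - \beta$, and on $\mu$, over a piecewise-constant
exposure schedule built from the smoking history (current smokers are
projected to continue smoking).

Writing $\Phi(s;t)$ for the probability that a cell initiated at time $s$
spawns no malignant cell by $t$, the backward Riccati equation
$d\Phi/ds = -(\alpha\Phi^2 - (\alpha+\beta+\mu)\Phi + \beta)$ with
$\Phi(t;t)=1$ has a closed form on each constant-parameter segment, and

$$S(t) = \exp\!\Big(-\int_0^t \nu(s)\,(1-\Phi(s;t))\,ds\Big)$$

assembles from segment-wise closed-form integrals. Numerical choices:

* the propagation uses the overflow-safe $e^{-D\tau}$ parameterization
  ($D = \sqrt{(\alpha+\beta+\mu)^2 - 4\alpha\beta} > 0$ whenever $\mu > 0$);
  the degenerate cases $\alpha = 0$ (linear ODE) and
  $\alpha = \beta,\ \mu = 0$ (double root) have their own closed forms, and
  a terminal value sitting exactly on a root is held constant;
* the hazard $h(t) = -d\log S/dt$ is computed by central differencing of the
  closed-form log-survival with step $10^{-5}$ y, which keeps agreement with
  analytic hazards well below $10^{-6}$;
* the tests cross-check the closed form against adaptive ODE integration
  (deSolve, tolerance $10^{-12}$) to $10^{-8}$, and against a Monte Carlo
  branching-process oracle (inhomogeneous-Poisson initiation plus
  segment-aware Gillespie clone simulation) within pointwise 99% binomial
  bands across random small-parameter configurations;
* the lag is a deterministic shift: risk at age $a$ reflects malignant
  conversion by $a - \mathrm{lag}$.

Interval risk is $1 - S(a+h)/S(a)$; by survival multiplicativity this equals
the composed annual-cycle form, and the tests assert that identity. Over a
cohort, subjects are evaluated in a vectorized three-segment pass rather
than per-subject loops.

## Validation metrics

* **Calibration.** Decile-grouped mean predicted risk versus observed
  proportion (plot data); the calibration slope is the coefficient of
  `qlogis(p)` in a logistic fit of the outcome, and calibration-in-the-large
  is the intercept of a logistic fit with `qlogis(p)` as a
  fixed-coefficient-1 offset. For outcomes generated from a logit-scale
  distortion $a + b\,\mathrm{logit}(p)$, the slope estimates $b$; the
  in-the-large intercept estimates the shift matching the distorted event
  rate, which equals $a$ exactly when $b = 1$ (the unconstrained fit's
  intercept, also returned, estimates $a$ directly but with much larger
  sampling error since it extrapolates to logit 0).
* **Discrimination.** AUC as the midrank concordance estimator (ties count
  one half), with a DeLong placement-value confidence interval. The test
  suite checks it against brute-force pair counting and against pROC.
* **Classification.** Sensitivity and specificity from eligibility counts,
  with Wilson score intervals (the interval methods are declared choices;
  nothing downstream depends on them).
* **Count-matched thresholds.** The threshold selecting (up to ties) the
  same number of individuals as a comparator strategy is the n-th largest
  prediction; ties include all tied individuals and the realized count is
  reported. This matches strategies on *programme size*, so sensitivity
  comparisons are like-for-like.
* **Decision curves.** Net benefit $(TP - FP\cdot t/(1-t))/n$ over a
  threshold grid of 0.1%–20% in 0.1% steps (the resolution at which such
  threshold tables are reported). Both the weighting factor $t/(1-t)$ and
  the harm ratio $(1-t)/t$ are exposed as separate functions because the
  two reciprocal framings are easy to confuse. "Positive net benefit over
  the comparator" uses strict inequality on the grid.

Under multiple imputation, AUCs are pooled on the logit scale and
calibration statistics on the raw scale by Rubin's rules; net-benefit
differences are averaged across imputations before range detection.

## Chained-equation imputation

No imputation package is assumed: the chained equations are implemented
directly. Conditional families are logistic regression with an
asymptotic-posterior coefficient draw for binary variables; Bayesian linear
regression with predictive-mean matching (5 donors) for continuous ones, so
imputed values respect the bounded, skewed observed distributions; and
multinomial logistic (fitted probabilities) for categorical ones. Variables
are swept in increasing-missingness order; quit-years are drawn only for
former smokers with the structural zero enforced for current smokers;
recoding bounds (BMI 14–60, intensity ≤ 100) are enforced after each sweep;
observed cells are never modified; derived pack-years are refreshed after
completion. Near-separation (|coefficient| > 25) falls back to the MAP fit
rather than drawing from a degenerate posterior. Cross-cohort donor
imputation fits the variable's model on donor rows and draws for target
rows — the pneumonia-history case, measured in one trial only.

Defaults (m = 20, 10 sweeps) follow the reported analysis scale; the
workflow scripts use m = 5 to keep runtimes in seconds.

## The synthetic cohort generator

The generator emulates the published baseline summaries of the two trial
populations from declared parametric families: truncated-normal age,
log-normal BMI/intensity/quit-years, categorical race and education
frequencies, comorbidity probabilities logistic in pack-years, and smoking
duration derived from a start-age distribution (so duration correlates with
age, and with quit-years by construction). The NLST-like scenario applies
rejection sampling against the pack-year eligibility constraint, ages
55–74. Scenario targets are the published medians/IQRs (e.g. PLCO-arm
duration 28 (16–39) years, NLST-arm pack-years around 48 (39–66)), and the
tests assert the duration marginals within ±2 y (median) and ±3 y (IQR
endpoints).

Missingness is injected per field at the participant-weighted published
rates. A Gaussian-copula subject-level factor (loading `rho = 0.7`,
calibrated once) clusters non-response within individuals — as questionnaire
non-response does — which is what makes the complete-case fraction about
0.93 while independent blanking at the same marginal rates would give about
0.91. MAR injection replaces the latent factor with the rank-normal score
of a named, never-missing predictor, preserving the marginal rates.

Outcomes are simulated from a designated generating model (default
PLCOm2012) with an optional logit distortion $p' = \mathrm{plogis}(a + b\,
\mathrm{logit}(p))$ for calibration-recovery testing; lung-cancer death is a
Bernoulli sub-event of incidence with case fatality 0.5 (reflecting the
roughly half-of-cases death counts of such trial populations within six
years), so death always implies incidence.

What the generator does *not* emulate: the trials' true joint covariate
distribution (unpublished), screening effects (lead time, overdiagnosis,
CT-arm mortality reduction), time-to-event structure (outcomes are binary
at a fixed horizon), and intensity–duration dependence (intensity is drawn
independently given status, a deliberately minimal dependence structure).
Passing tests show the pipeline and the qualitative comparison are sound
under these declared conditions — not that any model attains a particular
AUC on real trial data.

## Problem sizes used by the tests and workflow

Property suites run at n = 4,000–50,000 where a law-of-large-numbers
argument needs headroom (calibration recovery at 50,000 with four outcome
replicates per distortion cell; the model-versus-criteria comparison at
40,000 across ten seeds; hygiene checks at 20,000), and at a few thousand
elsewhere. The Monte Carlo TSCE oracle uses 2,500 replicate tissue
histories per configuration at small rate constants. The numbered
`analysis/` scripts use 10,000–20,000-person cohorts and five imputations.
These sizes were chosen so each suite states its claim with comfortable
statistical margin while the whole set runs in a few minutes.

## Known limitations

* Stand-in payloads mean absolute risks from the non-PLCOm2012 models are
  structurally faithful but numerically synthetic.
* Horizon support is 5 or 6 years (plus single-cycle); fixed-horizon models
  return their native-frame risk unchanged when the requested horizon
  differs, used as a score — no rescaling is invented.
* Binary outcomes at a fixed horizon: no censoring-aware metrics, no
  net-reclassification indices, no cost-effectiveness modelling.
* The multinomial imputation draw uses fitted class probabilities without a
  parameter draw; its between-imputation variance is slightly understated
  for categorical variables.
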