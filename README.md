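# lcriskval

Comparative validation of absolute-risk prediction models for selecting
lung cancer screening candidates.

Screening guidelines admit people by age and pack-years (≥ 30 pack-years;
former smokers quit < 15 years ago). Risk prediction models use the full
risk-factor profile instead — age, detailed smoking history, comorbidities,
family history — and the question for screening policy is whether selecting
by modelled risk beats the pack-year rule, and over which risk thresholds.
This package is for biostatisticians and screening-policy researchers who
need that comparison as reproducible, tested machinery: config-driven
implementations of nine published model structures, the standard external
validation metrics, decision-curve analysis, chained-equation imputation,
and a synthetic cohort generator that emulates the two large US screening
trial populations (NLST, PLCO) so every stage runs without access-restricted
trial microdata.

## What is implemented

**Nine risk models behind one registry** (`predict_risk()`,
`predict_cohort()`):

| family | models | structure |
|---|---|---|
| logistic | PLCOm2012, simplified PLCOm2012 | inverse-logit of a centred linear predictor, with the published reciprocal-power intensity transform |
| odds-ratio | LLP, simplified LLP | age–sex baseline 5-y risk × covariate odds ratios, combined on the odds scale |
| annual-cycle | Bach, Knoke | 1-y hazards composed over the horizon, `risk = Σ S_lc(k)·S_death(k)·p_lc(k)`, covariates advancing each cycle |
| biological | TSCE incidence, TSCE CPS death, TSCE NHS/HPFS death | two-stage clonal expansion hazard (initiation ν, clonal expansion α−β, transformation μ, detection lag) under piecewise-constant smoking dose, solved in closed form segment-wise |

The PLCOm2012 payload transcribes its published coefficient table. All
other payloads are clearly-labelled synthetic stand-ins (`*_synthetic.yaml`,
`provenance: synthetic`) with the published structure and
plausibility-calibrated constants — see the methods vignette.

**Validation metrics** (`auc()` with DeLong CI,
`calibration_intercept_slope()`, `calibration_groups()`, `sens_spec()` with
Wilson CIs, `match_threshold_to_count()`), **decision curves**
(`net_benefit()`, `decision_curve()`, `positive_nb_range()`,
`threshold_odds()` / `harm_ratio()`, `interpret_nb_delta()`), **imputation**
(`impute_mice()`, `impute_with_donor()`, `rubin_pool()`), the **generator**
(`generate_cohort()`, `simulate_outcomes()`, `inject_missingness()`), and an
end-to-end pipeline (`run_validation()`).

Net benefit at risk threshold *t* follows the standard decision-curve form

```
NB(t) = (TP − FP · t/(1−t)) / n
```

where the weighting factor `t/(1−t)` is the threshold odds and its
reciprocal `(1−t)/t` — the harm ratio — says how much worse missing one
detectable cancer is valued than one unnecessary screen (39 at t = 2.5%).

## Worked example

```r
library(lcriskval)

coh <- generate_cohort(cohort_scenario("plco_like", 10000), seed = 7)
out <- simulate_outcomes(coh, "plcom2012", seed = 8)
p   <- predict_risk(coh, "plcom2012")$probability

auc(p, out$lc_incidence)[c("auc", "ci_lower", "ci_upper")]
#> $auc        0.8086564
#> $ci_lower   0.7749672
#> $ci_upper   0.8423456

calibration_intercept_slope(p, out$lc_incidence)[c("intercept", "slope")]
#> intercept 0.012   slope 0.991     # near (0, 1): outcomes came from this model

crit <- nlst_eligible(coh)                       # pack-year criteria
mt   <- match_threshold_to_count(p, sum(crit))   # same programme size
sens_spec(crit, out$lc_incidence)                # criteria: sens 71.5%, spec 69.3%
sens_spec(p >= mt$threshold, out$lc_incidence)   # model at 1.38%: sens 76.8%, spec 69.4%

positive_nb_range(p, out$lc_incidence, crit)
#> positive net benefit over the criteria from 0.1% to 20% (grid maximum)

interpret_nb_delta(0.002, 0.025)
#> $tp_gain_per_1000 2     $fp_reduction_per_1000 78
```

Read: on a 10,000-person PLCO-like synthetic cohort with outcomes generated
from PLCOm2012, the generating model discriminates well (AUC 0.81), is
calibrated (intercept ≈ 0, slope ≈ 1), and — matched to select the same
number of people as the pack-year criteria — finds 76.8% of the cases the
criteria's 71.5% would, at equal specificity. A net-benefit gain of 0.002
at the 2.5% threshold is worth 2 extra true positives, or 78 avoided false
positives, per 1,000 people assessed.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic
cohorts, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R   # cohorts + outcomes + missingness
Rscript analysis/02_impute_missing.R     # chained equations + donor transfer
Rscript analysis/03_predict_risks.R      # all nine models, example profile
Rscript analysis/04_validate_models.R    # AUC/calibration reports (pooled)
Rscript analysis/05_decision_curves.R    # decision curves, threshold ranges
```

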