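# Two-stage clonal expansion model for lung cancer INCIDENCE (fitted in the
# published literature to the NHS/HPFS cohorts). The published per-gender
# rate constants and dose-response coefficients are not reproduced here;
# this payload is a SYNTHETIC plausibility-calibrated stand-in: background
# rates give a never-smoker hazard of order 2-4 per 10,000 at age 70, and
# the dose responses (scaling initiation, net clonal expansion and
# malignant transformation with cigarettes/day) raise a lifelong 30/day
# smoker's hazard roughly 15-fold, with a 5-y lag from first malignant cell
# to detected cancer.
#
# Rates are per year; dose response: rate(d) = base * (1 + coef * d^power).
model_id: tsce_incidence
outcome: incidence
horizon: 1
type: tsce
provenance: synthetic
covariates: [age, gender, smoking_status, smoking_duration,
             smoking_intensity, years_since_quit]
params:
  male:
    nu: 0.35
    alpha: 3.055
    beta: 3.0
    mu: 1.0e-06
    lag: 5
    dose_response:
      nu: {coef: 0.08, power: 1.0}
      growth: {coef: 0.24, power: 0.5}
      mu: {coef: 0.03, power: 1.0}
  female:
    nu: 0.30
    alpha: 3.052
    beta: 3.0
    mu: 1.0e-06
    lag: 5
    dose_response:
      nu: {coef: 0.08, power: 1.0}
      growth: {coef: 0.24, power: 0.5}
      mu: {coef: 0.03, power: 1.0}
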