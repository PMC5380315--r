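# Simplified PLCOm2012 variant: age + smoking variables only. The published
# simplified refit is not publicly tabulated; this payload is a SYNTHETIC
# plausibility-calibrated stand-in that keeps the full model's smoking-term
# structure (including the reciprocal-power intensity transform) with a
# recentred intercept, so that pipeline behaviour (covariate reduction,
# discrimination loss relative to the full model) is faithful even though
# the constants are not the original refit.
model_id: plcom2012_simplified
outcome: incidence
horizon: 6
type: logistic
provenance: synthetic
covariates: [age, smoking_status, smoking_duration, smoking_intensity,
             years_since_quit]
intercept: -4.46
terms:
  age: {coef: 0.0789, center: 62}
  smoking_status_current: {coef: 0.31}
  smoking_duration: {coef: 0.0328, center: 27.6017}
  years_since_quit: {coef: -0.0312, center: 8.593417}
  intensity_transform: {coef: -1.88, center: 0.4021541613, divisor: 10, power: -1}
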