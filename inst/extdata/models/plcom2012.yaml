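# PLCOm2012: logistic model for 6-y lung cancer incidence in ever-smokers.
# Coefficients transcribed from the original publication
# (Tammemagi MC et al., N Engl J Med 2013;368:728-36, model 1 for
# ever-smokers). Smoking intensity enters through the published
# reciprocal-power transform ((cigs/day / 10)^-1, centered).
model_id: plcom2012
outcome: incidence
horizon: 6
type: logistic
provenance: published
covariates: [age, race, education, bmi, copd, personal_history_cancer,
             family_history_lc, smoking_status, smoking_duration,
             smoking_intensity, years_since_quit]
intercept: -4.532506
terms:
  age: {coef: 0.0778868, center: 62}
  education: {coef: -0.0812744, center: 4}
  bmi: {coef: -0.0274194, center: 27}
  copd: {coef: 0.3553063}
  personal_history_cancer: {coef: 0.4589971}
  family_history_lc: {coef: 0.587185}
  smoking_status_current: {coef: 0.2597431}
  smoking_duration: {coef: 0.0317321, center: 27.6017}
  years_since_quit: {coef: -0.0308572, center: 8.593417}
  intensity_transform: {coef: -1.822606, center: 0.4021541613, divisor: 10, power: -1}
race_coefs:
  white: 0.0
  black: 0.3944778
  hispanic: -0.7434744
  asian: -0.466585
  pacific_islander: 1.027152
  native_american: 0.0
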