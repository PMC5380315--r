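# Bach model structure: annual lung-cancer hazard and annual competing
# (non-lung-cancer) death hazard composed over 1-y cycles, with age,
# duration, quit-years and current smoking advancing per cycle (Bach PB et
# al., J Natl Cancer Inst 2003; CARET). The original publication's spline
# coefficient set is not reproduced here; this payload is a SYNTHETIC
# plausibility-calibrated stand-in: log-linear annual hazards
# (complementary-log-log link) calibrated to heavy-smoker magnitudes
# (annual lung-cancer hazard of order 3-4 per 1,000 at age 62 after 40
# pack-years; annual competing mortality of order 1%).
model_id: bach
outcome: incidence
horizon: 1
type: annual_cycle
provenance: synthetic
competing_mortality: true
covariates: [age, smoking_status, smoking_duration, smoking_intensity,
             years_since_quit]
lc_hazard:
  intercept: -8.20
  age: 0.070
  age_center: 62
  duration: 0.052
  log_intensity: 0.58
  quit_years: -0.048
death_hazard:
  intercept: -5.55
  age: 0.085
  age_center: 62
  log_intensity: 0.28
  quit_years: -0.015
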