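# Knoke model structure: published log-hazard function of age, smoking
# duration, intensity and time since quitting for lung cancer DEATH,
# evaluated on a yearly grid and composed as 1 - prod(1 - p_k) with
# covariates advanced per cycle (Knoke JD et al., CPS-I). The original
# coefficient set is not reproduced here; this payload is a SYNTHETIC
# plausibility-calibrated stand-in on the same structure (no competing
# mortality term, per the published form).
model_id: knoke
outcome: death
horizon: 1
type: annual_cycle
provenance: synthetic
competing_mortality: false
covariates: [age, smoking_status, smoking_duration, smoking_intensity,
             years_since_quit]
lc_hazard:
  intercept: -8.95
  age: 0.075
  age_center: 62
  duration: 0.058
  log_intensity: 0.55
  quit_years: -0.040
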