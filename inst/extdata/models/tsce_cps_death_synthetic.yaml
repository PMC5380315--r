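# Two-stage clonal expansion model for lung cancer DEATH (published fits to
# the British Doctors and Cancer Prevention Studies). SYNTHETIC
# plausibility-calibrated stand-in (see tsce_incidence_synthetic.yaml);
# death is calibrated lower than incidence and carries a longer lag from
# first malignant cell to death.
model_id: tsce_cps_death
outcome: death
horizon: 1
type: tsce
provenance: synthetic
covariates: [age, gender, smoking_status, smoking_duration,
             smoking_intensity, years_since_quit]
params:
  male:
    nu: 0.22
    alpha: 3.050
    beta: 3.0
    mu: 1.0e-06
    lag: 7
    dose_response:
      nu: {coef: 0.07, power: 1.0}
      growth: {coef: 0.22, power: 0.5}
      mu: {coef: 0.025, power: 1.0}
  female:
    nu: 0.19
    alpha: 3.048
    beta: 3.0
    mu: 1.0e-06
    lag: 7
    dose_response:
      nu: {coef: 0.07, power: 1.0}
      growth: {coef: 0.22, power: 0.5}
      mu: {coef: 0.025, power: 1.0}
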