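# Two-stage clonal expansion model for lung cancer DEATH (published fits to
# the NHS/HPFS cohorts). SYNTHETIC plausibility-calibrated stand-in (see
# tsce_incidence_synthetic.yaml) with a slightly stronger promotion dose
# response than the CPS death fit, so the two death fits differ as distinct
# published calibrations do.
model_id: tsce_nhs_hpfs_death
outcome: death
horizon: 1
type: tsce
provenance: synthetic
covariates: [age, gender, smoking_status, smoking_duration,
             smoking_intensity, years_since_quit]
params:
  male:
    nu: 0.20
    alpha: 3.052
    beta: 3.0
    mu: 1.0e-06
    lag: 7
    dose_response:
      nu: {coef: 0.06, power: 1.0}
      growth: {coef: 0.26, power: 0.5}
      mu: {coef: 0.022, power: 1.0}
  female:
    nu: 0.17
    alpha: 3.050
    beta: 3.0
    mu: 1.0e-06
    lag: 7
    dose_response:
      nu: {coef: 0.06, power: 1.0}
      growth: {coef: 0.26, power: 0.5}
      mu: {coef: 0.022, power: 1.0}
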