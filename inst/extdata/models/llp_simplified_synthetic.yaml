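# Simplified LLP variant: age, sex and smoking duration only. SYNTHETIC
# stand-in calibrated the same way as llp_synthetic.yaml (structure fitted
# to a large synthetic development cohort), with the non-smoking covariate
# ORs dropped and the baseline raised slightly to absorb them.
model_id: llp_simplified
outcome: incidence
horizon: 5
type: llp_odds
provenance: synthetic
covariates: [age, gender, smoking_duration]
baseline_risk:
  bands:
    - {min: 18, male: 0.0005, female: 0.0005}
    - {min: 50, male: 0.0011, female: 0.0011}
    - {min: 55, male: 0.0015, female: 0.0015}
    - {min: 60, male: 0.0021, female: 0.0021}
    - {min: 65, male: 0.0024, female: 0.0024}
    - {min: 70, male: 0.0030, female: 0.0030}
    - {min: 75, male: 0.0036, female: 0.0036}
    - {min: 80, male: 0.0039, female: 0.0039}
odds_ratios:
  smoking_duration:
    - {min: 0,  or: 1.0}
    - {min: 1,  or: 1.4}
    - {min: 11, or: 2.0}
    - {min: 21, or: 3.7}
    - {min: 31, or: 7.0}
    - {min: 41, or: 14.2}
    - {min: 51, or: 27.4}
    - {min: 61, or: 42.8}
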