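# Liverpool Lung Project (LLP) structure: 5-y age-sex baseline absolute risk
# combined multiplicatively (on the odds scale) with covariate odds ratios
# (Cassidy A et al., Br J Cancer 2008). The published baseline table and OR
# estimates are not reproduced here; this payload is a SYNTHETIC stand-in
# with the published model's structure (age-sex baseline, categorical
# smoking-duration ORs, prior-malignancy, family-history by onset age,
# pneumonia and asbestos ORs), calibrated by fitting that structure to a
# large synthetic development cohort — mirroring how the original model was
# fitted to its case-control data. The duration gradient is steeper than the
# original publication's because, in the synthetic joint distribution,
# duration also proxies years-since-quit and lifetime exposure.
model_id: llp
outcome: incidence
horizon: 5
type: llp_odds
provenance: synthetic
covariates: [age, gender, smoking_duration, personal_history_cancer,
             family_history_lc, history_pneumonia]
baseline_risk:
  bands:                       # 5-y baseline absolute risk (duration 0)
    - {min: 18, male: 0.0004, female: 0.0004}
    - {min: 50, male: 0.0010, female: 0.0010}
    - {min: 55, male: 0.0014, female: 0.0014}
    - {min: 60, male: 0.0019, female: 0.0019}
    - {min: 65, male: 0.0022, female: 0.0022}
    - {min: 70, male: 0.0028, female: 0.0028}
    - {min: 75, male: 0.0033, female: 0.0033}
    - {min: 80, male: 0.0036, female: 0.0036}
odds_ratios:
  smoking_duration:            # ORs by years smoked, increasing
    - {min: 0,  or: 1.0}
    - {min: 1,  or: 1.4}
    - {min: 11, or: 2.0}
    - {min: 21, or: 3.6}
    - {min: 31, or: 6.8}
    - {min: 41, or: 13.8}
    - {min: 51, or: 26.6}
    - {min: 61, or: 41.5}
  personal_history_cancer: 1.50
  family_history_early: 2.50   # relative diagnosed at or before 60
  family_history_late: 2.03    # relative diagnosed after 60 (default map)
  history_pneumonia: 1.05
  asbestos: 1.89
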