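# ILLUSTRATIVE Quan-style Charlson Comorbidity Index mapping -- a reduced,
# NON-AUTHORITATIVE template showing the configuration shape (condition code
# sets, integer weights, hierarchy pairs where the severer condition
# suppresses the milder). Substitute a validated mapping for real analyses.
conditions:
  myocardial_infarction:
    weight: 1
    codes:
      - {system: ICD9, code: "410", prefix: true}
      - {system: ICD10, code: I21, prefix: true}
  congestive_heart_failure:
    weight: 1
    codes:
      - {system: ICD9, code: "428", prefix: true}
      - {system: ICD10, code: I50, prefix: true}
  peripheral_vascular_disease:
    weight: 1
    codes:
      - {system: ICD9, code: "443", prefix: true}
      - {system: ICD10, code: I73, prefix: true}
  chronic_pulmonary_disease:
    weight: 1
    codes:
      - {system: ICD9, code: "491", prefix: true}
      - {system: ICD9, code: "492", prefix: true}
      - {system: ICD9, code: "496"}
      - {system: ICD10, code: J43, prefix: true}
      - {system: ICD10, code: J44, prefix: true}
  dementia:
    weight: 1
    codes:
      - {system: ICD9, code: "290", prefix: true}
      - {system: ICD9, code: "3310"}
      - {system: ICD10, code: F01, prefix: true}
      - {system: ICD10, code: F02, prefix: true}
      - {system: ICD10, code: F03, prefix: true}
      - {system: ICD10, code: G30, prefix: true}
  diabetes:
    weight: 1
    codes:
      - {system: ICD9, code: "2500", prefix: true}
      - {system: ICD10, code: E119}
  diabetes_complications:
    weight: 2
    codes:
      - {system: ICD9, code: "2504", prefix: true}
      - {system: ICD9, code: "2505", prefix: true}
      - {system: ICD9, code: "2506", prefix: true}
      - {system: ICD9, code: "2507", prefix: true}
      - {system: ICD10, code: E112, prefix: true}
      - {system: ICD10, code: E113, prefix: true}
      - {system: ICD10, code: E114, prefix: true}
      - {system: ICD10, code: E115, prefix: true}
  renal_disease:
    weight: 2
    codes:
      - {system: ICD9, code: "585", prefix: true}
      - {system: ICD10, code: N18, prefix: true}
  mild_liver_disease:
    weight: 1
    codes:
      - {system: ICD9, code: "5715", prefix: true}
      - {system: ICD10, code: K74, prefix: true}
  severe_liver_disease:
    weight: 3
    codes:
      - {system: ICD9, code: "5722", prefix: true}
      - {system: ICD10, code: K72, prefix: true}
  cancer:
    weight: 2
    codes:
      - {system: ICD9, code: "153", prefix: true}
      - {system: ICD9, code: "162", prefix: true}
      - {system: ICD9, code: "174", prefix: true}
      - {system: ICD10, code: C18, prefix: true}
      - {system: ICD10, code: C34, prefix: true}
      - {system: ICD10, code: C50, prefix: true}
  metastatic_cancer:
    weight: 6
    codes:
      - {system: ICD9, code: "196", prefix: true}
      - {system: ICD9, code: "197", prefix: true}
      - {system: ICD9, code: "198", prefix: true}
      - {system: ICD10, code: C77, prefix: true}
      - {system: ICD10, code: C78, prefix: true}
      - {system: ICD10, code: C79, prefix: true}
hierarchy:
  - {milder: diabetes, severer: diabetes_complications}
  - {milder: mild_liver_disease, severer: severe_liver_disease}
  - {milder: cancer, severer: metastatic_cancer}
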