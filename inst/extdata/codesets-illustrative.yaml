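# ILLUSTRATIVE phenotype code sets -- a plausible, editable template, NOT an
# authoritative clinical code list. Real analyses must supply their own
# configuration. Matching is system-aware; prefix entries match any code
# starting with the value.
AD:
  - {system: ICD9, code: "3310"}
  - {system: ICD10, code: G30, prefix: true}
dementia:
  - {system: ICD9, code: "290", prefix: true}
  - {system: ICD10, code: F01, prefix: true}
  - {system: ICD10, code: F02, prefix: true}
  - {system: ICD10, code: F03, prefix: true}
agitation:
  - {system: ICD9, code: "7992", prefix: true}
  - {system: ICD10, code: R455, prefix: true}
  - {system: ICD10, code: R456, prefix: true}
  - {system: ICD10, code: R463, prefix: true}
bipolar:
  - {system: ICD9, code: "2964", prefix: true}
  - {system: ICD9, code: "2965", prefix: true}
  - {system: ICD9, code: "2966", prefix: true}
  - {system: ICD10, code: F31, prefix: true}
MDD:
  - {system: ICD9, code: "2962", prefix: true}
  - {system: ICD9, code: "2963", prefix: true}
  - {system: ICD10, code: F32, prefix: true}
  - {system: ICD10, code: F33, prefix: true}
schizophrenia:
  - {system: ICD9, code: "295", prefix: true}
  - {system: ICD10, code: F20, prefix: true}
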