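{
  "unit_costs": {
    "dermatologist_consult": 28.88,
    "gp_consult": 23.67,
    "excision_first": 54.10,
    "excision_additional": 27.05,
    "pathology": 62.02,
    "immunohistochemistry_per_stain": 25.41,
    "optical_dermoscopy": 6.39,
    "sddi_exam": 23.22
  },
  "group1": {
    "n_screened": 7434,
    "n_unnecessary_patients": 533,
    "n_multi_patients": 33,
    "total_unnecessary_excisions": 570,
    "n_melanomas": 70
  },
  "group2": {
    "n_screened": 1926,
    "n_unnecessary_patients": 79,
    "n_multi_patients": 0,
    "total_unnecessary_excisions": 79,
    "n_melanomas": 32,
    "n_sddi_registered": 124,
    "n_attended_3month": 124,
    "n_attended_12month": 90
  },
  "psa": {
    "n_iterations": 10000,
    "seed": 1
  },
  "output": {
    "directory": ".",
    "formats": ["csv", "json"]
  }
}
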