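{
  "_comment": "Synthetic example risk-model configuration. Relative risks are of published meta-analysis magnitude but are NOT the proprietary coefficients of any deployed FRAX tool; substitute literature values for realistic output.",
  "relative_risks": {
    "factor": ["prior_fracture", "parental_hip_fracture", "current_smoking",
               "glucocorticoids", "rheumatoid_arthritis",
               "secondary_osteoporosis", "alcohol_excess"],
    "hip": [1.85, 2.27, 1.60, 2.01, 1.73, 1.60, 1.70],
    "mof": [1.76, 1.54, 1.29, 1.57, 1.45, 1.35, 1.38]
  },
  "gradient_of_risk": {"hip": 2.6, "mof": 1.6},
  "reference_tscore": 0,
  "rr_per_bmi_unit": 1,
  "secondary_osteoporosis_inactive_with_bmd": true
}
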