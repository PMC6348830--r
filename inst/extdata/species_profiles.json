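{
  "_comment": "Whole-body masses are the cohort means of the three study populations. Organ masses and blood volumes are ASSUMED reference values (ICRP-style adult human; literature mouse and juvenile pig), shipped because mass-based scaling needs them; override for serious use. Masses in kg, blood volume in mL.",
  "mouse": {
    "m_wb": 0.026,
    "organ_masses": { "kidneys": 0.0004, "liver": 0.0013 }
  },
  "pig": {
    "m_wb": 28,
    "organ_masses": { "kidneys": 0.13, "liver": 0.9 },
    "blood_volume_ml": 1850
  },
  "human": {
    "m_wb": 61,
    "organ_masses": { "kidneys": 0.31, "liver": 1.8 },
    "blood_volume_ml": 5300
  }
}
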