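{
  "_comment": "Synthetic Lorentzian peak library. Positions are literature-plausible 1H chemical shifts used as fixture constants for spectral simulation; half-widths < 0.03 ppm mark narrow (low molecular weight) resonances, broader entries mark lipid envelopes.",
  "alanine": [
    {"center": 1.48, "halfWidth": 0.010, "amplitude": 1.0},
    {"center": 3.78, "halfWidth": 0.010, "amplitude": 0.33}
  ],
  "lactic_acid": [
    {"center": 1.33, "halfWidth": 0.010, "amplitude": 1.0},
    {"center": 4.12, "halfWidth": 0.010, "amplitude": 0.33}
  ],
  "glucose": [
    {"center": 3.24, "halfWidth": 0.012, "amplitude": 0.4},
    {"center": 3.41, "halfWidth": 0.012, "amplitude": 0.6},
    {"center": 3.72, "halfWidth": 0.012, "amplitude": 0.5},
    {"center": 3.90, "halfWidth": 0.012, "amplitude": 0.3},
    {"center": 5.24, "halfWidth": 0.010, "amplitude": 0.2}
  ],
  "valine": [
    {"center": 0.99, "halfWidth": 0.009, "amplitude": 1.0},
    {"center": 1.04, "halfWidth": 0.009, "amplitude": 1.0}
  ],
  "leucine": [
    {"center": 0.96, "halfWidth": 0.009, "amplitude": 1.0}
  ],
  "isoleucine": [
    {"center": 0.94, "halfWidth": 0.009, "amplitude": 0.7},
    {"center": 1.01, "halfWidth": 0.009, "amplitude": 0.5}
  ],
  "tyrosine": [
    {"center": 6.89, "halfWidth": 0.010, "amplitude": 0.5},
    {"center": 7.19, "halfWidth": 0.010, "amplitude": 0.5}
  ],
  "histidine": [
    {"center": 7.05, "halfWidth": 0.010, "amplitude": 0.4},
    {"center": 7.75, "halfWidth": 0.010, "amplitude": 0.4}
  ],
  "glutamine": [
    {"center": 2.14, "halfWidth": 0.011, "amplitude": 0.6},
    {"center": 2.45, "halfWidth": 0.011, "amplitude": 0.6}
  ],
  "glycine": [
    {"center": 3.56, "halfWidth": 0.009, "amplitude": 1.0}
  ],
  "creatine": [
    {"center": 3.03, "halfWidth": 0.009, "amplitude": 0.8},
    {"center": 3.93, "halfWidth": 0.009, "amplitude": 0.5}
  ],
  "creatinine": [
    {"center": 3.05, "halfWidth": 0.009, "amplitude": 0.8},
    {"center": 4.06, "halfWidth": 0.009, "amplitude": 0.5}
  ],
  "citric_acid": [
    {"center": 2.54, "halfWidth": 0.011, "amplitude": 0.6},
    {"center": 2.66, "halfWidth": 0.011, "amplitude": 0.6}
  ],
  "pyruvic_acid": [
    {"center": 2.37, "halfWidth": 0.009, "amplitude": 1.0}
  ],
  "acetic_acid": [
    {"center": 1.92, "halfWidth": 0.009, "amplitude": 1.0}
  ],
  "triglycerides": [
    {"center": 0.88, "halfWidth": 0.060, "amplitude": 0.9},
    {"center": 1.28, "halfWidth": 0.070, "amplitude": 1.2},
    {"center": 2.02, "halfWidth": 0.060, "amplitude": 0.4},
    {"center": 5.31, "halfWidth": 0.050, "amplitude": 0.2}
  ],
  "cholesterol": [
    {"center": 0.68, "halfWidth": 0.040, "amplitude": 0.5},
    {"center": 0.92, "halfWidth": 0.050, "amplitude": 0.7}
  ],
  "ldl_cholesterol": [
    {"center": 0.84, "halfWidth": 0.050, "amplitude": 0.6},
    {"center": 1.26, "halfWidth": 0.060, "amplitude": 0.7}
  ],
  "hdl_cholesterol": [
    {"center": 0.80, "halfWidth": 0.050, "amplitude": 0.5},
    {"center": 1.24, "halfWidth": 0.060, "amplitude": 0.5}
  ],
  "apo_a1": [
    {"center": 0.86, "halfWidth": 0.080, "amplitude": 0.4}
  ],
  "apo_a2": [
    {"center": 0.87, "halfWidth": 0.080, "amplitude": 0.3}
  ],
  "apo_b100": [
    {"center": 0.89, "halfWidth": 0.080, "amplitude": 0.4}
  ]
}
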