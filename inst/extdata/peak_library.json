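[
  {"name": "lipoprotein_CH3", "positions": [0.85, 0.89], "relative_amplitudes": [1.0, 0.6], "linewidth": 0.025, "baseline": 8.0},
  {"name": "lipoprotein_CH2", "positions": [1.25, 1.29], "relative_amplitudes": [1.0, 0.5], "linewidth": 0.03, "baseline": 12.0},
  {"name": "saturated_lipid", "positions": [1.57, 2.24], "relative_amplitudes": [1.0, 0.7], "linewidth": 0.03, "baseline": 3.0},
  {"name": "allylic_lipid", "positions": [2.00, 2.76], "relative_amplitudes": [1.0, 0.4], "linewidth": 0.03, "baseline": 2.5},
  {"name": "unsaturated_lipid", "positions": [5.30, 5.33], "relative_amplitudes": [1.0, 0.8], "linewidth": 0.025, "baseline": 2.0},
  {"name": "lactate", "positions": [1.324, 1.336, 4.10, 4.12], "relative_amplitudes": [1.0, 1.0, 0.2, 0.2], "linewidth": 0.004, "baseline": 10.0},
  {"name": "threonine", "positions": [1.314, 1.326, 3.58, 4.24], "relative_amplitudes": [0.5, 0.5, 0.2, 0.2], "linewidth": 0.004, "baseline": 1.2},
  {"name": "beta_hydroxybutyrate", "positions": [1.19, 1.21, 2.30, 2.40], "relative_amplitudes": [0.5, 0.5, 0.2, 0.2], "linewidth": 0.004, "baseline": 0.8},
  {"name": "NAC1", "positions": [2.04], "relative_amplitudes": [1.0], "linewidth": 0.012, "baseline": 1.5},
  {"name": "NAC2", "positions": [2.07], "relative_amplitudes": [1.0], "linewidth": 0.012, "baseline": 1.0},
  {"name": "glucose", "positions": [3.24, 3.40, 3.46, 3.52, 3.72, 3.82, 3.89, 5.23], "relative_amplitudes": [0.6, 0.8, 0.7, 0.6, 0.9, 0.7, 0.5, 0.35], "linewidth": 0.005, "baseline": 5.0},
  {"name": "alanine", "positions": [1.46, 1.48], "relative_amplitudes": [0.5, 0.5], "linewidth": 0.004, "baseline": 1.5},
  {"name": "valine", "positions": [0.98, 1.03], "relative_amplitudes": [0.5, 0.5], "linewidth": 0.004, "baseline": 0.9},
  {"name": "leucine", "positions": [0.95, 0.96], "relative_amplitudes": [0.5, 0.5], "linewidth": 0.004, "baseline": 0.8},
  {"name": "isoleucine", "positions": [0.93, 1.00], "relative_amplitudes": [0.5, 0.4], "linewidth": 0.004, "baseline": 0.4},
  {"name": "glutamine", "positions": [2.12, 2.44], "relative_amplitudes": [0.5, 0.6], "linewidth": 0.006, "baseline": 2.0},
  {"name": "glutamate", "positions": [2.08, 2.34], "relative_amplitudes": [0.5, 0.5], "linewidth": 0.006, "baseline": 0.7},
  {"name": "citrate", "positions": [2.53, 2.65], "relative_amplitudes": [0.5, 0.5], "linewidth": 0.006, "baseline": 0.5},
  {"name": "creatinine", "positions": [3.04, 4.05], "relative_amplitudes": [0.6, 0.4], "linewidth": 0.005, "baseline": 0.6},
  {"name": "creatine", "positions": [3.03, 3.93], "relative_amplitudes": [0.6, 0.4], "linewidth": 0.005, "baseline": 0.4},
  {"name": "choline", "positions": [3.20], "relative_amplitudes": [1.0], "linewidth": 0.005, "baseline": 0.8},
  {"name": "glycine", "positions": [3.56], "relative_amplitudes": [1.0], "linewidth": 0.004, "baseline": 0.9},
  {"name": "acetate", "positions": [1.92], "relative_amplitudes": [1.0], "linewidth": 0.004, "baseline": 0.4},
  {"name": "pyruvate", "positions": [2.37], "relative_amplitudes": [1.0], "linewidth": 0.004, "baseline": 0.3},
  {"name": "acetone", "positions": [2.23], "relative_amplitudes": [1.0], "linewidth": 0.004, "baseline": 0.2},
  {"name": "methionine", "positions": [2.14, 2.64], "relative_amplitudes": [0.6, 0.4], "linewidth": 0.005, "baseline": 0.2},
  {"name": "histidine", "positions": [7.05, 7.77], "relative_amplitudes": [0.5, 0.5], "linewidth": 0.005, "baseline": 0.3},
  {"name": "tyrosine", "positions": [6.89, 7.19], "relative_amplitudes": [0.5, 0.5], "linewidth": 0.005, "baseline": 0.25},
  {"name": "phenylalanine", "positions": [7.33, 7.37, 7.42], "relative_amplitudes": [0.4, 0.4, 0.3], "linewidth": 0.005, "baseline": 0.25},
  {"name": "formate", "positions": [8.45], "relative_amplitudes": [1.0], "linewidth": 0.004, "baseline": 0.1}
]
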