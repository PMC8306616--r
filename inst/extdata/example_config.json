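{
  "panel": {
    "reactions": [
      {"reaction_id": "R1",
       "vic": {"chromosome": "13", "efficiency": 1.0},
       "fam": {"chromosome": "21", "efficiency": 1.0}},
      {"reaction_id": "R2",
       "vic": {"chromosome": "X", "efficiency": 1.0},
       "fam": {"chromosome": "18", "efficiency": 1.0}},
      {"reaction_id": "R3",
       "vic": {"chromosome": "X", "efficiency": 1.0},
       "fam": {"chromosome": "Y", "efficiency": 1.0}}
    ]
  },
  "thresholds": {
    "trisomy": {"euploid": [0.80, 1.25], "aneuploid": [1.35, 1.70]},
    "r18X_female": {"euploid": [0.80, 1.25], "aneuploid": [1.35, 1.70]},
    "r18X_male": {"euploid": [1.65, 2.48], "aneuploid": [2.52, 3.30]},
    "rX18_x0": [0.45, 0.60],
    "rXY": {"one": [0.75, 1.35], "two": [1.6, 2.4],
            "three": [2.6, 3.4], "half": [0.4, 0.65]},
    "y_presence_min": 0.1,
    "mosaic_policy": "flag"
  },
  "simulation": {
    "n_partitions": 20000,
    "lambda_base": 0.8,
    "invalid_fraction": 0.01,
    "per_molecule_detection_prob": 0.98,
    "false_positive_rate": 0.0001
  },
  "qc": {
    "min_valid_partitions": 10000,
    "ntc_max_positive_wells": 5,
    "saturation_min_negative_wells": 20
  }
}
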