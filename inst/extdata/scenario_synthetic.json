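{
  "comment": "Synthetic three-source scenario (NOT measured data): plausible humic-lake end members with known true fractions, for simulation and parameter recovery.",
  "true_fractions": {"peat": 0.40, "modern": 0.50, "atmosphere": 0.10},
  "end_members": [
    {"name": "peat",       "d13c": [-28.0, 1.0],  "f14c": [0.35, 0.15]},
    {"name": "modern",     "d13c": [-29.0, 1.0],  "f14c": [1.02, 0.02]},
    {"name": "atmosphere", "d13c": [-9.80, 0.10], "f14c": [1.01, 0.01]}
  ],
  "measurement_noise": {"d13c": 0.5, "f14c": 0.01},
  "n_replicates": 10,
  "seed": 1,
  "site": "synthetic-lake"
}
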