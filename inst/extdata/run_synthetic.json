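{
  "comment": "Synthetic demo run config (NOT measured data): plausible end members, a DIC-like mixture, both conceptual models, and flux upscaling.",
  "end_members": [
    {"name": "peat",       "d13c": [-28.0, 1.0],  "f14c": [0.35, 0.15]},
    {"name": "modern",     "d13c": [-29.0, 1.0],  "f14c": [1.02, 0.02]},
    {"name": "atmosphere", "d13c": [-9.80, 0.10], "f14c": [1.01, 0.01]}
  ],
  "mixture": {"label": "demo-lake", "d13c": [-23.5, 1.1], "f14c": [0.76, 0.02]},
  "model": "both",
  "n_iter": 20000,
  "seed": 42,
  "flux": {"areal_flux": [29, 60], "area": 2250}
}
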