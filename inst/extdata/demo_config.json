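{
  "generate": {
    "generating_model_id": 3,
    "replicates_per_condition": 4,
    "noise_cv": 0.21,
    "dt": 0.1
  },
  "model_id": 3,
  "run_selection": false,
  "split": { "fraction": 0.75, "n_density_strata": 2 },
  "calibration": { "n_starts": 4, "dt": 0.1, "maxfev": 400 },
  "level": 0.95
}
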