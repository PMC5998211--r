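{
  "synthetic": true,
  "seed": 1,
  "n_components": 3,
  "vip_threshold": 2.0,
  "rank_freq_threshold": 0.5,
  "verbosity": "info",
  "synthetic_config": {
    "n_case": 15,
    "n_control": 21,
    "n_markers": 232,
    "n_informative": 10,
    "n_batches": 2,
    "noise_sd": 0.5,
    "batch_scale_range": [0.5, 2.0],
    "seed": 1
  },
  "preprocess": {
    "log_base": 10,
    "log_offset": 0,
    "apply_batch_norm": true,
    "apply_log": true,
    "apply_pareto": true
  },
  "sbs": {
    "n_trees": 500,
    "elimination_fraction": 0.2,
    "min_subset": 2,
    "one_se_rule": true,
    "seed": 1001
  },
  "mccv": {
    "n_iterations": 50,
    "train_fraction": 0.7,
    "stratified": true,
    "seed": 2001
  }
}
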