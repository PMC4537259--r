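{
  "seed": 20260920,
  "stages": {
    "discrimination": true,
    "domains": false,
    "penetrance": true,
    "gait": true
  },
  "resample": {
    "n_repetitions": 100,
    "subsample_fraction": 0.8,
    "n_overlap_samples": 2000
  },
  "models": {
    "weak_model": {
      "cohort": {
        "n_control": 16,
        "n_mutant": 16,
        "n_features": 200,
        "block_sizes": [10, 10, 10, 10, 10, 10, 10, 10, 10, 10,
                        10, 10, 10, 10, 10, 10, 10, 10, 10, 10],
        "within_block_rho": 0.3,
        "effect_features": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
                            11, 12, 13, 14, 15, 16, 17, 18, 19, 20],
        "effect_size": 0.8,
        "trait_rho": 0.1,
        "penetrance_fraction": 1.0
      },
      "gait": {
        "n_per_group": 16,
        "exponent_b": -0.4,
        "scale_a": 0.5,
        "weight_slope": 3,
        "noise_sd": 0.05,
        "group_speed_shift": 0
      }
    },
    "strong_model": {
      "cohort": {
        "n_control": 16,
        "n_mutant": 16,
        "n_features": 200,
        "block_sizes": [10, 10, 10, 10, 10, 10, 10, 10, 10, 10,
                        10, 10, 10, 10, 10, 10, 10, 10, 10, 10],
        "within_block_rho": 0.3,
        "effect_features": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
                            11, 12, 13, 14, 15, 16, 17, 18, 19, 20],
        "effect_size": 2.5,
        "trait_rho": 0.1,
        "penetrance_fraction": 1.0
      },
      "gait": {
        "n_per_group": 16,
        "exponent_b": -0.4,
        "scale_a": 0.5,
        "weight_slope": 3,
        "noise_sd": 0.05,
        "group_speed_shift": 4
      }
    }
  }
}
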