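{
  "calibration": [
    [0.55, 0.4, 0.05],
    [0.25, 0.7, 0.05],
    [0.03, 0.07, 0.9]
  ],
  "discrimination_space": {
    "white_point": [0.6, 1],
    "axis_scale": [1, 1],
    "fundamentals": "synthetic-EEW"
  },
  "mondrian_space": {
    "white_point": [0.6, 1],
    "axis_scale": [1, 1],
    "fundamentals": "synthetic-illuminantC"
  },
  "filter_low": 15,
  "filter_high": 15000,
  "subsample_k": 5,
  "staircase": {
    "s_max": 1,
    "down": 0.5,
    "up": 1.5,
    "n_reversals": 18,
    "max_trials": 720,
    "second_start": "continue"
  },
  "mondrian": {
    "s_max": 0.5,
    "mean_luminance": 55,
    "lum_jitter": 0.5,
    "min_frac": 0.02,
    "max_frac": 0.17,
    "canvas_factor": 1.5,
    "max_elements": 5000
  },
  "n_perm": 10000
}
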