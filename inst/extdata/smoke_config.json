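{
  "participants": 2,
  "cycles": 1,
  "seed": 1,
  "pursuit": {
    "amplitudes_deg": [5, 10, 15],
    "frequencies_hz": [0.5, 1],
    "axes": ["horizontal", "vertical"]
  },
  "saccade": {
    "angles_deg": [2.5, 5, 7.5, 10, 12.5, 15],
    "directions": ["left", "right", "up", "down"]
  },
  "noise": {
    "white_uV": 2,
    "drift_uV_per_sqrt_s": 3,
    "line_50hz_uV": 5,
    "camera_noise_deg": 0.3,
    "camera_dropout_prob": 0.02,
    "camera_latency_s": 0.1
  },
  "deflection_mode": "flank",
  "cv_scheme": "loo"
}
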