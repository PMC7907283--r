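{
  "preset": "mixed_demo",
  "seed": 7,
  "out_dir": "out",
  "log_level": "info",
  "simulation": {
    "n_cases": 2,
    "rois_per_case": 3
  }
}
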