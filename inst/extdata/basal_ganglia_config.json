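{
  "inputs": {"IN": {"SC": "1", "Thalamus": "1"}},
  "background": {"Thalamus": "1/2"},
  "comparison_mode": "at_least",
  "output_layer": [],
  "note": "background and comparison_mode are inferred by calibration (bg_calibrate), not printed in the published model"
}
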