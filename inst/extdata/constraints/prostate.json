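{
  "source_label": "illustrative prostate example set (placeholder, not a protocol)",
  "constraints": [
    { "structure": "Rectum", "metric": "V70Gy", "comparator": "LE", "pass_limit": 20, "variation_limit": 25 },
    { "structure": "Rectum", "metric": "V65Gy", "comparator": "LE", "pass_limit": 35, "variation_limit": 40 },
    { "structure": "Bladder", "metric": "V70Gy", "comparator": "LE", "pass_limit": 30, "variation_limit": 35 },
    { "structure": "Femur_Head_L", "metric": "Dmax", "comparator": "LE", "pass_limit": 50, "variation_limit": 52 },
    { "structure": "Femur_Head_R", "metric": "Dmax", "comparator": "LE", "pass_limit": 50, "variation_limit": 52 },
    { "structure": "PTV", "metric": "D95%", "comparator": "GE", "pass_limit": 74.1, "variation_limit": 70.2 }
  ]
}
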