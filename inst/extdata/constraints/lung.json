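{
  "source_label": "illustrative lung example set (placeholder, not a protocol)",
  "constraints": [
    { "structure": "Lungs", "metric": "V20Gy", "comparator": "LE", "pass_limit": 35, "variation_limit": 37 },
    { "structure": "Lungs", "metric": "Dmean", "comparator": "LE", "pass_limit": 20, "variation_limit": 21 },
    { "structure": "SpinalCord", "metric": "Dmax", "comparator": "LE", "pass_limit": 45, "variation_limit": 50 },
    { "structure": "Heart", "metric": "V40Gy", "comparator": "LE", "pass_limit": 35, "variation_limit": 40 },
    { "structure": "Esophagus", "metric": "Dmean", "comparator": "LE", "pass_limit": 34, "variation_limit": 36 },
    { "structure": "PTV", "metric": "D95%", "comparator": "GE", "pass_limit": 57, "variation_limit": 54 }
  ]
}
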