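{
  "version": "three-tier localized prostate risk, config 1.0",
  "t_order": ["T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4"],
  "low": { "t_max": "T2a", "gleason_sum_max": 6, "psa_max_exclusive": 10 },
  "high": { "t_min": "T3a", "gleason_sum_min": 8, "psa_min_exclusive": 20 }
}
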