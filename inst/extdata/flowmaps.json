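{
  "version": "1.0",
  "flows": [
    { "site": "PROSTATE", "from": "CONSULT.t_stage", "to": "EOT.t_stage" },
    { "site": "LUNG", "from": "CONSULT.t_stage", "to": "EOT.t_stage" }
  ]
}
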