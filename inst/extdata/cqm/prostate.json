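{
  "ruleset_id": "prostate_example",
  "version": "1.0 (structural illustration, not a published measure set)",
  "feature_dictionary": [
    "record.disease_site", "record.risk_group", "record.hormone_therapy",
    "record.treatment_intent", "record.treatment_completed",
    "record.psa", "record.t_stage",
    "plan.prescription_dose", "plan.fractions", "plan.dose_per_fraction",
    "plan.technique",
    "dvh.Rectum.V70Gy.status", "dvh.Bladder.V70Gy.status", "dvh.plan_status"
  ],
  "measures": [
    {
      "measure_id": "PR-ADT",
      "title": "High-risk patients receive androgen deprivation therapy",
      "category": "EXPECTED",
      "root": "n_risk",
      "nodes": {
        "n_risk": { "field": "record.risk_group", "op": "EQ", "value": "HIGH",
                    "true": "n_adt", "false": "leaf_na" },
        "n_adt": { "field": "record.hormone_therapy", "op": "EQ", "value": true,
                   "true": "leaf_pass", "false": "leaf_fail" },
        "leaf_pass": { "result": "PASS" },
        "leaf_fail": { "result": "FAIL" },
        "leaf_na": { "result": "NOT_APPLICABLE" }
      }
    },
    {
      "measure_id": "PR-DOSE",
      "title": "Curative-intent prescription of at least 70 Gy equivalent",
      "category": "EXPECTED",
      "root": "n_intent",
      "nodes": {
        "n_intent": { "field": "record.treatment_intent", "op": "EQ",
                      "value": "CURATIVE", "true": "n_fx", "false": "leaf_na" },
        "n_fx": { "field": "plan.dose_per_fraction", "op": "GE", "value": 2.4,
                  "true": "leaf_pass", "false": "n_dose" },
        "n_dose": { "field": "plan.prescription_dose", "op": "GE", "value": 70,
                    "true": "leaf_pass", "false": "leaf_fail" },
        "leaf_pass": { "result": "PASS" },
        "leaf_fail": { "result": "FAIL" },
        "leaf_na": { "result": "NOT_APPLICABLE" }
      }
    },
    {
      "measure_id": "PR-RECTUM",
      "title": "Rectum V70Gy within protocol or acceptable variation",
      "category": "EXPECTED",
      "root": "n_status",
      "nodes": {
        "n_status": { "field": "dvh.Rectum.V70Gy.status", "op": "IN",
                      "value": ["PASS", "VARIATION"],
                      "true": "leaf_pass", "false": "leaf_fail" },
        "leaf_pass": { "result": "PASS" },
        "leaf_fail": { "result": "FAIL" }
      }
    },
    {
      "measure_id": "PR-COMPLETE",
      "title": "Prescribed course completed",
      "category": "SURVEILLANCE",
      "root": "n_done",
      "nodes": {
        "n_done": { "field": "record.treatment_completed", "op": "EQ",
                    "value": true, "true": "leaf_pass", "false": "leaf_fail" },
        "leaf_pass": { "result": "PASS" },
        "leaf_fail": { "result": "FAIL" }
      }
    }
  ]
}
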