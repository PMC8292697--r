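{
  "ruleset_id": "lung_example",
  "version": "1.0 (structural illustration, not a published measure set)",
  "feature_dictionary": [
    "record.disease_site", "record.treatment_intent",
    "record.treatment_completed", "record.motion_management",
    "plan.prescription_dose", "plan.fractions", "plan.technique",
    "dvh.Lungs.V20Gy.status", "dvh.SpinalCord.Dmax.status", "dvh.plan_status"
  ],
  "measures": [
    {
      "measure_id": "LU-V20",
      "title": "Lung V20Gy not in violation",
      "category": "EXPECTED",
      "root": "n_status",
      "nodes": {
        "n_status": { "field": "dvh.Lungs.V20Gy.status", "op": "NE",
                      "value": "FAIL", "true": "leaf_pass", "false": "leaf_fail" },
        "leaf_pass": { "result": "PASS" },
        "leaf_fail": { "result": "FAIL" }
      }
    },
    {
      "measure_id": "LU-MOTION",
      "title": "SBRT delivered with motion management",
      "category": "EXPECTED",
      "root": "n_sbrt",
      "nodes": {
        "n_sbrt": { "field": "plan.technique", "op": "EQ", "value": "SBRT",
                    "true": "n_mm", "false": "leaf_na" },
        "n_mm": { "field": "record.motion_management", "op": "NE",
                  "value": "NONE", "true": "leaf_pass", "false": "leaf_fail" },
        "leaf_pass": { "result": "PASS" },
        "leaf_fail": { "result": "FAIL" },
        "leaf_na": { "result": "NOT_APPLICABLE" }
      }
    },
    {
      "measure_id": "LU-CORD",
      "title": "Spinal cord maximum dose within limit",
      "category": "EXPECTED",
      "root": "n_status",
      "nodes": {
        "n_status": { "field": "dvh.SpinalCord.Dmax.status", "op": "IN",
                      "value": ["PASS", "VARIATION"],
                      "true": "leaf_pass", "false": "leaf_fail" },
        "leaf_pass": { "result": "PASS" },
        "leaf_fail": { "result": "FAIL" }
      }
    },
    {
      "measure_id": "LU-COMPLETE",
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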