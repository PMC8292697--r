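{
  "version": "1.0",
  "schemas": [
    {
      "template_id": "CONSULT",
      "disease_site": "PROSTATE",
      "fields": [
        { "name": "age", "type": "number", "required": true, "min": 18, "max": 110, "unit": "years" },
        { "name": "ecog", "type": "vocab", "required": true, "vocabulary": "ecog" },
        { "name": "t_stage", "type": "vocab", "required": true, "vocabulary": "ajcc_t_prostate" },
        { "name": "n_stage", "type": "vocab", "required": true, "vocabulary": "ajcc_n_prostate" },
        { "name": "m_stage", "type": "vocab", "required": true, "vocabulary": "ajcc_m_prostate" },
        { "name": "gleason_primary", "type": "integer", "required": true, "min": 3, "max": 5 },
        { "name": "gleason_secondary", "type": "integer", "required": true, "min": 3, "max": 5 },
        { "name": "psa", "type": "number", "required": true, "min": 0, "max": 5000, "unit": "ng/mL" },
        { "name": "risk_group", "type": "vocab", "required": true, "vocabulary": "nccn_risk" },
        { "name": "treatment_intent", "type": "vocab", "required": true, "vocabulary": "treatment_intent" },
        { "name": "hormone_therapy", "type": "boolean", "required": true },
        { "name": "comorbidity", "type": "text", "required": false }
      ]
    },
    {
      "template_id": "SIM_DIRECTIVE",
      "disease_site": "PROSTATE",
      "fields": [
        { "name": "target_name", "type": "text", "required": true },
        { "name": "prescription_dose_gy", "type": "number", "required": true, "min": 20, "max": 90, "unit": "Gy" },
        { "name": "fractions", "type": "integer", "required": true, "min": 1, "max": 45 },
        { "name": "technique", "type": "vocab", "required": true, "vocabulary": "technique" },
        { "name": "immobilization", "type": "text", "required": false }
      ]
    },
    {
      "template_id": "OTV",
      "disease_site": "PROSTATE",
      "fields": [
        { "name": "otv_week", "type": "integer", "required": true, "min": 1, "max": 12 },
        { "name": "gu_toxicity_grade", "type": "vocab", "required": true, "vocabulary": "ctcae_grade" },
        { "name": "gi_toxicity_grade", "type": "vocab", "required": true, "vocabulary": "ctcae_grade" }
      ]
    },
    {
      "template_id": "EOT",
      "disease_site": "PROSTATE",
      "fields": [
        { "name": "total_dose_delivered_gy", "type": "number", "required": true, "min": 0, "max": 120, "unit": "Gy" },
        { "name": "fractions_delivered", "type": "integer", "required": true, "min": 0, "max": 60 },
        { "name": "treatment_completed", "type": "boolean", "required": true },
        { "name": "t_stage", "type": "vocab", "required": true, "vocabulary": "ajcc_t_prostate" },
        { "name": "eot_gu_toxicity_grade", "type": "vocab", "required": true, "vocabulary": "ctcae_grade" },
        { "name": "eot_gi_toxicity_grade", "type": "vocab", "required": true, "vocabulary": "ctcae_grade" }
      ]
    },
    {
      "template_id": "FOLLOWUP",
      "disease_site": "PROSTATE",
      "fields": [
        { "name": "months_since_rt", "type": "number", "required": true, "min": 0, "max": 240 },
        { "name": "fu_psa", "type": "number", "required": true, "min": 0, "max": 5000, "unit": "ng/mL" },
        { "name": "recurrence", "type": "boolean", "required": true },
        { "name": "late_gi_toxicity_grade", "type": "vocab", "required": true, "vocabulary": "ctcae_grade" }
      ]
    },
    {
      "template_id": "CONSULT",
      "disease_site": "LUNG",
      "fields": [
        { "name": "age", "type": "number", "required": true, "min": 18, "max": 110, "unit": "years" },
        { "name": "ecog", "type": "vocab", "required": true, "vocabulary": "ecog" },
        { "name": "t_stage", "type": "vocab", "required": true, "vocabulary": "ajcc_t_lung" },
        { "name": "n_stage", "type": "vocab", "required": true, "vocabulary": "ajcc_n_lung" },
        { "name": "m_stage", "type": "vocab", "required": true, "vocabulary": "ajcc_m_lung" },
        { "name": "histology", "type": "vocab", "required": true, "vocabulary": "histology_lung" },
        { "name": "smoking_status", "type": "vocab", "required": true, "vocabulary": "smoking_status" },
        { "name": "fev1_pct", "type": "number", "required": true, "min": 10, "max": 150, "unit": "% predicted" },
        { "name": "treatment_intent", "type": "vocab", "required": true, "vocabulary": "treatment_intent" },
        { "name": "comorbidity", "type": "text", "required": false }
      ]
    },
    {
      "template_id": "SIM_DIRECTIVE",
      "disease_site": "LUNG",
      "fields": [
        { "name": "target_name", "type": "text", "required": true },
        { "name": "prescription_dose_gy", "type": "number", "required": true, "min": 20, "max": 90, "unit": "Gy" },
        { "name": "fractions", "type": "integer", "required": true, "min": 1, "max": 45 },
        { "name": "technique", "type": "vocab", "required": true, "vocabulary": "technique" },
        { "name": "motion_management", "type": "vocab", "required": true, "vocabulary": "motion_management" }
      ]
    },
    {
      "template_id": "OTV",
      "disease_site": "LUNG",
      "fields": [
        { "name": "otv_week", "type": "integer", "required": true, "min": 1, "max": 12 },
        { "name": "esophagitis_grade", "type": "vocab", "required": true, "vocabulary": "ctcae_grade" },
        { "name": "dyspnea_grade", "type": "vocab", "required": true, "vocabulary": "ctcae_grade" },
        { "name": "weight_loss_pct", "type": "number", "required": true, "min": 0, "max": 50 }
      ]
    },
    {
      "template_id": "EOT",
      "disease_site": "LUNG",
      "fields": [
        { "name": "total_dose_delivered_gy", "type": "number", "required": true, "min": 0, "max": 120, "unit": "Gy" },
        { "name": "fractions_delivered", "type": "integer", "required": true, "min": 0, "max": 60 },
        { "name": "treatment_completed", "type": "boolean", "required": true },
        { "name": "t_stage", "type": "vocab", "required": true, "vocabulary": "ajcc_t_lung" },
        { "name": "eot_esophagitis_grade", "type": "vocab", "required": true, "vocabulary": "ctcae_grade" }
      ]
    },
    {
      "template_id": "FOLLOWUP",
      "disease_site": "LUNG",
      "fields": [
        { "name": "months_since_rt", "type": "number", "required": true, "min": 0, "max": 240 },
        { "name": "pneumonitis_grade", "type": "vocab", "required": true, "vocabulary": "ctcae_grade" },
        { "name": "recurrence", "type": "boolean", "required": true }
      ]
    }
  ]
}
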