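END OF TREATMENT SUMMARY

The patient completed external beam radiotherapy to a delivered dose of {total_dose_delivered_gy} Gy in {fractions_delivered} fractions. Course completed as prescribed: {treatment_completed}. Clinical stage at consult: {EOT.t_stage}. Acute GU toxicity at completion: grade {eot_gu_toxicity_grade}. Acute GI toxicity at completion: grade {eot_gi_toxicity_grade}.
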