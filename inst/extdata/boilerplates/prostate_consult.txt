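RADIATION ONCOLOGY CONSULT NOTE

The patient is a {age} year old man with clinically localized prostate cancer, ECOG performance status {ecog}. Clinical stage {t_stage} {n_stage} {m_stage}. Biopsy Gleason score {gleason_primary} + {gleason_secondary}. PSA was {psa} ng/mL. NCCN risk group: {risk_group}. Relevant comorbidity: {comorbidity}.

Treatment intent is {treatment_intent}. Androgen deprivation therapy planned: {hormone_therapy}.
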