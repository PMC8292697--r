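{
  "version": "1.0",
  "vocabularies": {
    "ajcc_t_prostate": {
      "source": "AJCC 8th edition, clinical T, prostate",
      "values": ["T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4"]
    },
    "ajcc_n_prostate": { "source": "AJCC 8th edition", "values": ["N0", "N1"] },
    "ajcc_m_prostate": { "source": "AJCC 8th edition", "values": ["M0", "M1"] },
    "ajcc_t_lung": {
      "source": "AJCC 8th edition, clinical T, lung",
      "values": ["T1a", "T1b", "T1c", "T2a", "T2b", "T3", "T4"]
    },
    "ajcc_n_lung": { "source": "AJCC 8th edition", "values": ["N0", "N1", "N2", "N3"] },
    "ajcc_m_lung": { "source": "AJCC 8th edition", "values": ["M0", "M1a", "M1b", "M1c"] },
    "ecog": { "source": "ECOG performance status", "values": [0, 1, 2, 3, 4] },
    "ctcae_grade": { "source": "CTCAE v5.0", "values": [0, 1, 2, 3, 4, 5] },
    "nccn_risk": { "source": "NCCN prostate, three-tier", "values": ["LOW", "INTERMEDIATE", "HIGH"] },
    "treatment_intent": { "source": "local", "values": ["CURATIVE", "PALLIATIVE"] },
    "technique": { "source": "local", "values": ["3DCRT", "IMRT", "VMAT", "SBRT"] },
    "histology_lung": {
      "source": "local",
      "values": ["ADENOCARCINOMA", "SQUAMOUS", "SMALL_CELL", "NSCLC_NOS"]
    },
    "smoking_status": { "source": "local", "values": ["CURRENT", "FORMER", "NEVER"] },
    "motion_management": { "source": "local", "values": ["NONE", "4DCT_ITV", "GATING", "ABC"] }
  }
}
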