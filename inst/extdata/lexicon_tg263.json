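{
  "version": "starter lexicon 1.0 (prostate + lung)",
  "entries": [
    { "tg263_name": "Bladder", "category": "OAR", "synonyms": ["urinary bladder", "blad", "bladder wall"] },
    { "tg263_name": "Rectum", "category": "OAR", "synonyms": ["rect", "rectal wall", "rektum"] },
    { "tg263_name": "Prostate", "category": "TARGET", "synonyms": ["prost", "prostate gland"] },
    { "tg263_name": "SeminalVes", "category": "TARGET", "synonyms": ["seminal vesicles", "sem ves", "sv"] },
    { "tg263_name": "PenileBulb", "category": "OAR", "synonyms": ["penile bulb", "bulb"] },
    { "tg263_name": "Femur_Head_L", "category": "OAR", "synonyms": ["left femoral head", "l femoral head", "femhead lt"] },
    { "tg263_name": "Femur_Head_R", "category": "OAR", "synonyms": ["right femoral head", "r femoral head", "femhead rt"] },
    { "tg263_name": "Bowel_Small", "category": "OAR", "synonyms": ["small bowel", "small intestine"] },
    { "tg263_name": "Bowel_Large", "category": "OAR", "synonyms": ["large bowel", "colon"] },
    { "tg263_name": "Sigmoid", "category": "OAR", "synonyms": ["sigmoid colon"] },
    { "tg263_name": "Urethra", "category": "OAR", "synonyms": ["urethra prox"] },
    { "tg263_name": "CaudaEquina", "category": "OAR", "synonyms": ["cauda equina"] },
    { "tg263_name": "Lung_L", "category": "OAR", "synonyms": ["left lung", "l lung", "lung lt"] },
    { "tg263_name": "Lung_R", "category": "OAR", "synonyms": ["right lung", "r lung", "lung rt"] },
    { "tg263_name": "Lungs", "category": "OAR", "synonyms": ["both lungs", "total lung", "lungs-gtv", "bilateral lungs"] },
    { "tg263_name": "Heart", "category": "OAR", "synonyms": ["cor", "whole heart"] },
    { "tg263_name": "Esophagus", "category": "OAR", "synonyms": ["oesophagus", "esoph"] },
    { "tg263_name": "SpinalCord", "category": "OAR", "synonyms": ["spinal cord", "cord"] },
    { "tg263_name": "SpinalCanal", "category": "OAR", "synonyms": ["spinal canal", "canal"] },
    { "tg263_name": "BrachialPlex_L", "category": "OAR", "synonyms": ["left brachial plexus", "l brachial plexus"] },
    { "tg263_name": "BrachialPlex_R", "category": "OAR", "synonyms": ["right brachial plexus", "r brachial plexus"] },
    { "tg263_name": "Trachea", "category": "OAR", "synonyms": ["windpipe"] },
    { "tg263_name": "Bronchus_Prox", "category": "OAR", "synonyms": ["proximal bronchial tree", "prox bronchus"] },
    { "tg263_name": "GreatVes", "category": "OAR", "synonyms": ["great vessels"] },
    { "tg263_name": "Chestwall", "category": "OAR", "synonyms": ["chest wall", "thoracic wall"] },
    { "tg263_name": "Ribs", "category": "OAR", "synonyms": ["rib cage"] },
    { "tg263_name": "Liver", "category": "OAR", "synonyms": ["hepar"] },
    { "tg263_name": "Stomach", "category": "OAR", "synonyms": ["gaster"] },
    { "tg263_name": "Kidney_L", "category": "OAR", "synonyms": ["left kidney", "l kidney"] },
    { "tg263_name": "Kidney_R", "category": "OAR", "synonyms": ["right kidney", "r kidney"] },
    { "tg263_name": "Duodenum", "category": "OAR", "synonyms": [] },
    { "tg263_name": "Skin", "category": "OAR", "synonyms": ["derma"] },
    { "tg263_name": "Body", "category": "OAR", "synonyms": ["external", "outer contour", "patient"] },
    { "tg263_name": "GTV", "category": "TARGET", "synonyms": ["gross tumor volume", "gross target volume"] },
    { "tg263_name": "CTV", "category": "TARGET", "synonyms": ["clinical target volume"] },
    { "tg263_name": "PTV", "category": "TARGET", "synonyms": ["planning target volume"] },
    { "tg263_name": "ITV", "category": "TARGET", "synonyms": ["internal target volume"] },
    { "tg263_name": "LN_Pelvic", "category": "TARGET", "synonyms": ["pelvic lymph nodes", "pelvic nodes"] },
    { "tg263_name": "Bone_Pelvic", "category": "OAR", "synonyms": ["pelvic bones", "pelvis bones"] },
    { "tg263_name": "Bag_Bowel", "category": "OAR", "synonyms": ["bowel bag", "peritoneal cavity"] }
  ]
}
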