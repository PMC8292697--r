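{
  "version": "1.0 (Safe-Harbor-style identifier categories as configuration)",
  "mandatory_identifiers": ["name", "mrn", "dob", "address", "phone"],
  "record_fields": {
    "name": "REMOVE",
    "mrn": "HASH_PSEUDONYM",
    "dob": "SHIFT_DATE",
    "address": "REMOVE",
    "phone": "REMOVE"
  },
  "dicom_tags": {
    "PatientName": "REPLACE_DUMMY",
    "PatientID": "HASH_PSEUDONYM",
    "PatientBirthDate": "REMOVE",
    "StudyDate": "SHIFT_DATE"
  },
  "uid_root": "2.25",
  "date_shift_range": 90
}
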