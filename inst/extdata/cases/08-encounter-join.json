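{
  "title": "encounter view with getReferenceKey(Patient) under the display key strategy",
  "resourceFile": "../resources/example-resources-synthetic.json",
  "viewFile": "../views/encounter_join.json",
  "keyStrategy": "display",
  "expect": [
    {"encounter_id": "encounter-1", "patient_id": "patient-1", "encounter_date": "2023-01-01"},
    {"encounter_id": "encounter-2", "patient_id": "patient-2", "encounter_date": "2023-02-15"},
    {"encounter_id": "encounter-3", "patient_id": "patient-1", "encounter_date": "2023-03-10"}
  ]
}
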