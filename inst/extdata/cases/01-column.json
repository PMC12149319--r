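{
  "title": "column selection: id and birth date, one row per patient",
  "resourceFile": "../resources/example-resources-synthetic.json",
  "viewFile": "../views/patient_demographics.json",
  "expect": [
    {"id": "patient-1", "birth_date": "1980-01-01"},
    {"id": "patient-2", "birth_date": "1992-07-15"},
    {"id": "patient-3", "birth_date": "1965-12-31"}
  ]
}
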