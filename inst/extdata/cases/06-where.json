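{
  "title": "where active = true keeps only the two active patients",
  "resourceFile": "../resources/example-resources-synthetic.json",
  "viewFile": "../views/active_patients.json",
  "expect": [
    {"id": "patient-1", "given_name": "Aisha", "family_name": "Khan"},
    {"id": "patient-3", "given_name": "Wei", "family_name": "Zhang"}
  ]
}
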