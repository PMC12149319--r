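{
  "title": "patient view with getResourceKey() under the display key strategy",
  "resourceFile": "../resources/example-resources-synthetic.json",
  "viewFile": "../views/patient_join.json",
  "keyStrategy": "display",
  "expect": [
    {"patient_id": "patient-1", "name": "Aisha", "family": "Khan"},
    {"patient_id": "patient-2", "name": "Juan", "family": "Rodriguez"},
    {"patient_id": "patient-3", "name": "Wei", "family": "Zhang"}
  ]
}
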