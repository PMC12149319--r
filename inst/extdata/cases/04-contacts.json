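{
  "title": "name columns cross-joined with one row per phone number",
  "resourceFile": "../resources/example-resources-synthetic.json",
  "viewFile": "../views/patient_contacts.json",
  "expect": [
    {"id": "patient-1", "name": "Aisha", "family": "Khan", "contact_phone": "555551234"},
    {"id": "patient-1", "name": "Aisha", "family": "Khan", "contact_phone": "555559876"},
    {"id": "patient-2", "name": "Juan", "family": "Rodriguez", "contact_phone": "555542233"},
    {"id": "patient-3", "name": "Wei", "family": "Zhang", "contact_phone": "555554321"},
    {"id": "patient-3", "name": "Wei", "family": "Zhang", "contact_phone": "555555678"}
  ]
}
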