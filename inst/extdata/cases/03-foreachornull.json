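{
  "title": "forEachOrNull over addresses: addressless patient keeps one null row",
  "resourceFile": "../resources/example-resources-synthetic.json",
  "viewFile": "../views/patient_addresses_or_null.json",
  "expect": [
    {"id": "patient-1", "address_line": "1 Main St", "address_city": "Springfield", "address_state": "IL", "address_postal_code": "62701"},
    {"id": "patient-1", "address_line": "42 Second Ave", "address_city": "Chicago", "address_state": "IL", "address_postal_code": "60601"},
    {"id": "patient-1", "address_line": "789 Third St", "address_city": "Peoria", "address_state": "IL", "address_postal_code": "61602"},
    {"id": "patient-2", "address_line": null, "address_city": null, "address_state": null, "address_postal_code": null},
    {"id": "patient-3", "address_line": "42 Second Ave", "address_city": "Chicago", "address_state": "IL", "address_postal_code": "60601"}
  ]
}
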