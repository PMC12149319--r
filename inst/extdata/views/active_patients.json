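{
  "name": "active_patients",
  "version": "1.0.0",
  "url": "http://example.org/fhir/ViewDefinition/active_patients",
  "meta": {
    "profile": [
      "http://sql-on-fhir.org/StructureDefinition/ShareableViewDefinition",
      "http://sql-on-fhir.org/StructureDefinition/TabularViewDefinition"
    ]
  },
  "fhirVersion": "4.0.1",
  "resource": "Patient",
  "select": [
    {
      "column": [
        {"name": "id", "path": "id", "type": "id"},
        {"name": "given_name", "path": "name.first().given.first()", "type": "string"},
        {"name": "family_name", "path": "name.first().family", "type": "string"}
      ]
    }
  ],
  "where": [
    {"path": "active = true", "description": "active patients only"}
  ]
}
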