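{
  "name": "patient_demographics",
  "version": "1.0.0",
  "url": "http://example.org/fhir/ViewDefinition/patient_demographics",
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
        {"name": "birth_date", "path": "birthDate", "type": "date"}
      ]
    }
  ]
}
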