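{
  "name": "patient_addresses_or_null",
  "version": "1.0.0",
  "url": "http://example.org/fhir/ViewDefinition/patient_addresses_or_null",
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
        {"name": "id", "path": "id", "type": "id"}
      ]
    },
    {
      "forEachOrNull": "address",
      "column": [
        {"name": "address_line", "path": "line.first()", "type": "string"},
        {"name": "address_city", "path": "city", "type": "string"},
        {"name": "address_state", "path": "state", "type": "string"},
        {"name": "address_postal_code", "path": "postalCode", "type": "string"}
      ]
    }
  ]
}
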