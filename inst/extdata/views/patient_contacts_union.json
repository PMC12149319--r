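{
  "name": "patient_contacts_union",
  "version": "1.0.0",
  "url": "http://example.org/fhir/ViewDefinition/patient_contacts_union",
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
        {"name": "name", "path": "name.first().given.first()", "type": "string"},
        {"name": "family", "path": "name.first().family", "type": "string"}
      ],
      "unionAll": [
        {
          "forEach": "telecom.where(system = 'phone' and use = 'home')",
          "column": [
            {"name": "contact_phone", "path": "value", "type": "string"}
          ]
        },
        {
          "forEach": "telecom.where(system = 'phone' and use = 'work')",
          "column": [
            {"name": "contact_phone", "path": "value", "type": "string"}
          ]
        }
      ]
    }
  ]
}
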