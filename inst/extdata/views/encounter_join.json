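{
  "name": "encounter_join",
  "version": "1.0.0",
  "url": "http://example.org/fhir/ViewDefinition/encounter_join",
  "meta": {
    "profile": [
      "http://sql-on-fhir.org/StructureDefinition/ShareableViewDefinition",
      "http://sql-on-fhir.org/StructureDefinition/TabularViewDefinition"
    ]
  },
  "fhirVersion": "4.0.1",
  "resource": "Encounter",
  "select": [
    {
      "column": [
        {"name": "encounter_id", "path": "getResourceKey()", "type": "string"},
        {"name": "patient_id", "path": "subject.getReferenceKey(Patient)", "type": "string"},
        {"name": "encounter_date", "path": "period.start", "type": "date"}
      ]
    }
  ]
}
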