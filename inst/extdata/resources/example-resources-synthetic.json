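[
  {
    "resourceType": "Patient",
    "id": "patient-1",
    "active": true,
    "name": [
      {
        "use": "official",
        "family": "Khan",
        "given": [
          "Aisha"
        ]
      }
    ],
    "birthDate": "1980-01-01",
    "address": [
      {
        "use": "home",
        "line": [
          "1 Main St"
        ],
        "city": "Springfield",
        "state": "IL",
        "postalCode": "62701"
      },
      {
        "use": "work",
        "line": [
          "42 Second Ave"
        ],
        "city": "Chicago",
        "state": "IL",
        "postalCode": "60601"
      },
      {
        "use": "temp",
        "line": [
          "789 Third St"
        ],
        "city": "Peoria",
        "state": "IL",
        "postalCode": "61602"
      }
    ],
    "telecom": [
      {
        "system": "phone",
        "value": "555551234",
        "use": "home"
      },
      {
        "system": "phone",
        "value": "555559876",
        "use": "work"
      }
    ]
  },
  {
    "resourceType": "Patient",
    "id": "patient-2",
    "active": false,
    "name": [
      {
        "use": "official",
        "family": "Rodriguez",
        "given": [
          "Juan"
        ]
      }
    ],
    "birthDate": "1992-07-15",
    "telecom": [
      {
        "system": "phone",
        "value": "555542233",
        "use": "home"
      }
    ]
  },
  {
    "resourceType": "Patient",
    "id": "patient-3",
    "active": true,
    "name": [
      {
        "use": "official",
        "family": "Zhang",
        "given": [
          "Wei"
        ]
      }
    ],
    "birthDate": "1965-12-31",
    "address": [
      {
        "use": "home",
        "line": [
          "42 Second Ave"
        ],
        "city": "Chicago",
        "state": "IL",
        "postalCode": "60601"
      }
    ],
    "telecom": [
      {
        "system": "phone",
        "value": "555554321",
        "use": "home"
      },
      {
        "system": "phone",
        "value": "555555678",
        "use": "work"
      }
    ]
  },
  {
    "resourceType": "Encounter",
    "id": "encounter-1",
    "status": "finished",
    "class": {
      "system": "http://terminology.hl7.org/CodeSystem/v3-ActCode",
      "code": "AMB"
    },
    "subject": {
      "reference": "Patient/patient-1"
    },
    "period": {
      "start": "2023-01-01"
    }
  },
  {
    "resourceType": "Encounter",
    "id": "encounter-2",
    "status": "finished",
    "class": {
      "system": "http://terminology.hl7.org/CodeSystem/v3-ActCode",
      "code": "AMB"
    },
    "subject": {
      "reference": "Patient/patient-2"
    },
    "period": {
      "start": "2023-02-15"
    }
  },
  {
    "resourceType": "Encounter",
    "id": "encounter-3",
    "status": "finished",
    "class": {
      "system": "http://terminology.hl7.org/CodeSystem/v3-ActCode",
      "code": "AMB"
    },
    "subject": {
      "reference": "Patient/patient-1"
    },
    "period": {
      "start": "2023-03-10"
    }
  }
]
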