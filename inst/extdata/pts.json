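{
  "metabolites": [
    {"id": "glc", "name": "glucose", "is_cofactor": false, "is_external": true},
    {"id": "pep", "name": "phosphoenolpyruvate", "is_cofactor": false, "is_external": false},
    {"id": "g6p", "name": "glucose-6-phosphate", "is_cofactor": false, "is_external": false},
    {"id": "pyr", "name": "pyruvate", "is_cofactor": false, "is_external": false},
    {"id": "atp", "name": "ATP", "is_cofactor": true, "is_external": false},
    {"id": "adp", "name": "ADP", "is_cofactor": true, "is_external": false}
  ],
  "reactions": [
    {"id": "pts", "substrates": {"pep": 1, "glc": 1}, "products": {"g6p": 1, "pyr": 1}, "reversible": false},
    {"id": "lower_glycolysis", "substrates": {"g6p": 1, "adp": 2}, "products": {"pep": 2, "atp": 2}, "reversible": false}
  ]
}
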