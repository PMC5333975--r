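{
  "metabolites": [
    {"id": "glc", "name": "glucose", "is_cofactor": false, "is_external": true},
    {"id": "atp", "name": "ATP", "is_cofactor": false, "is_external": false},
    {"id": "adp", "name": "ADP", "is_cofactor": false, "is_external": false},
    {"id": "tp", "name": "triose phosphate", "is_cofactor": false, "is_external": false},
    {"id": "pyr", "name": "pyruvate", "is_cofactor": false, "is_external": false}
  ],
  "reactions": [
    {"id": "priming", "substrates": {"glc": 1, "atp": 2}, "products": {"tp": 2, "adp": 2}, "reversible": false},
    {"id": "payoff", "substrates": {"tp": 1, "adp": 2}, "products": {"pyr": 1, "atp": 2}, "reversible": false}
  ]
}
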