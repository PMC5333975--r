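{
  "metabolites": [
    {"id": "c5", "name": "five-carbon sugar pool (RuBP equivalents)", "is_cofactor": false, "is_external": false},
    {"id": "co2", "name": "carbon dioxide", "is_cofactor": false, "is_external": true}
  ],
  "reactions": [
    {"id": "cbb_lump", "substrates": {"c5": 5, "co2": 5}, "products": {"c5": 6}, "reversible": false}
  ]
}
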