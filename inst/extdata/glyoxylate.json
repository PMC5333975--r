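{
  "metabolites": [
    {"id": "mal", "name": "malate", "is_cofactor": false, "is_external": false},
    {"id": "icit", "name": "isocitrate", "is_cofactor": false, "is_external": false},
    {"id": "accoa", "name": "acetyl-CoA", "is_cofactor": false, "is_external": true}
  ],
  "reactions": [
    {"id": "mal_to_icit", "substrates": {"mal": 1, "accoa": 1}, "products": {"icit": 1}, "reversible": false},
    {"id": "icl_mas", "substrates": {"icit": 1, "accoa": 1}, "products": {"mal": 2}, "reversible": false}
  ]
}
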