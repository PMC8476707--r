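{
  "name": "empty-with-multimers",
  "seed": 23,
  "n_ions": 10000,
  "mixture": [
    {"label": "empty", "kind": "empty", "weight": 0.954},
    {"label": "dimer-compact", "kind": "multimer", "weight": 0.030, "multimer_order": 2},
    {"label": "dimer-extended", "kind": "multimer", "weight": 0.008, "multimer_order": 2,
     "charge_shape_factor": 1.26},
    {"label": "trimer", "kind": "multimer", "weight": 0.008, "multimer_order": 3}
  ],
  "analysis": {"classify": false, "fit_components": false, "counterion_fit": false}
}
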