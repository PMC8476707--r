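{
  "name": "reference-standard",
  "seed": 19,
  "n_ions": 10000,
  "dna": {"inflation": 1.0, "offset": 0},
  "constructs": [
    {"name": "AAV8-RSS", "n_bases": 3400}
  ],
  "mixture": [
    {"label": "full", "kind": "full_GOI", "weight": 0.86},
    {"label": "partial", "kind": "partial", "weight": 0.14,
     "partial_dist": "truncnorm", "partial_mean": 0.64, "partial_sd": 0.12}
  ],
  "analysis": {"classify": true, "fit_components": true, "counterion_fit": false, "window_sd": 55000}
}
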