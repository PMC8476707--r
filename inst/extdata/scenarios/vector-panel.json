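{
  "name": "vector-panel",
  "seed": 7,
  "n_ions": 10000,
  "capsid": {"vp_masses": [81667, 66692, 59805], "ratio": [1, 1, 10], "n_subunits": 60},
  "instrument": {"trap_time": 100, "sigma_z_ref": 1, "rel_sigma_mz": 0.001, "bin_width": 20000,
                 "multiple_ion_rate": 0.05, "short_trap_rate": 0.02},
  "charge_model": {"z_ref": 150, "m_ref": 3.7e6},
  "dna": {"per_base_mass": 307.97, "inflation": 1.0, "offset": 0},
  "constructs": [
    {"name": "CMV-CRE", "n_bases": 2219},
    {"name": "CMV-GFP", "n_bases": 2544},
    {"name": "CMV-mCherry", "n_bases": 2784},
    {"name": "CAG-GFP", "n_bases": 2876},
    {"name": "CAG-mCherry", "n_bases": 2895},
    {"name": "EF1a-GFP", "n_bases": 3458},
    {"name": "CBA-GFP", "n_bases": 4354},
    {"name": "CMV-SaCas9", "n_bases": 4844}
  ],
  "mixture": [
    {"label": "empty", "kind": "empty", "weight": 0.12},
    {"label": "partial", "kind": "partial", "weight": 0.10},
    {"label": "full", "kind": "full_GOI", "weight": 0.63},
    {"label": "headful", "kind": "headful", "weight": 0.15, "capacity_sd": 50000}
  ],
  "analysis": {"classify": true, "fit_components": true, "counterion_fit": false, "window_sd": 55000}
}
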