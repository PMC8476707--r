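name	n_bases	expected_mass_MDa
Empty	0	0
CMV-CRE	2219	0.683
CMV-GFP	2544	0.783
CMV-mCherry	2784	0.857
CAG-GFP	2876	0.886
CAG-mCherry	2895	0.892
EF1a-GFP	3458	1.065
CBA-GFP	4354	1.341
CMV-SaCas9	4844	1.492
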