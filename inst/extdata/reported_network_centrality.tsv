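network	dc_mean	dc_sd	bc_mean	bc_sd
Parieto-frontal	5.07	0.95	0.72	0.26
Temporo-frontal	3.66	1.08	2.75	0.84
Posterior-medial	4.38	1.03	3.47	1.08
Somato-motor	7.69	1.20	1.36	0.32
Visu	4.66	0.96	0.60	0.41
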