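abbreviation	network	dc_mean	dc_ci_low	dc_ci_high	bc_mean	bc_ci_low	bc_ci_high
f2_2	Parieto-frontal	5.99	5.75	6.22	1.35	1.06	1.64
F3t	Temporo-frontal	5.08	4.67	5.49	4.14	3.09	5.19
STS4	Temporo-frontal	5.04	4.65	5.43	3.62	2.07	4.54
INSa3	Temporo-frontal	4.86	4.41	5.31	3.59	2.78	4.40
PRECU1	Posterior-medial	6.11	5.90	6.33	5.30	4.58	6.02
pos2	Posterior-medial	5.82	5.58	6.07	4.59	3.97	5.20
post2	Somato-motor	9.27	8.86	9.68	1.68	1.40	1.95
cing4	Somato-motor	9.40	9.04	9.76	1.90	1.59	2.21
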