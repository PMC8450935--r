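protein	RN	delta_T	V_ex	V_shell	N_shell	eta	pmv
TisAFP6	222	0.08	34.57	95.58	2266	0.114	16.61
PaAFP	37	0.10	5.78	43.71	1329	0.051	2.30
ZaAFP	66	0.18	11.50	48.07	1305	0.071	5.35
TisAFP8	223	0.36	34.46	95.85	2254	0.102	16.98
CfAFP337	87	1.34	13.81	53.16	1417	0.081	6.40
TmAFP	82	2.22	12.24	49.87	1358	0.082	5.48
RiAFP	139	3.43	21.16	75.82	1983	0.089	9.82
CfAFP501	120	4.28	19.11	66.18	1707	0.088	9.01
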