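protein	S_WP	S_IBS	fpho_WP	fpho_IBS	fpho_NIBS
TisAFP6	99.87	10.11	0.56	0.56	0.56
PaAFP	30.31	7.60	0.54	0.64	0.51
ZaAFP	40.09	8.17	0.58	0.67	0.56
TisAFP8	98.25	10.70	0.59	0.70	0.57
CfAFP337	48.56	8.02	0.52	0.58	0.51
TmAFP	42.68	7.57	0.46	0.61	0.42
RiAFP	72.97	15.46	0.52	0.54	0.52
CfAFP501	62.85	8.66	0.49	0.67	0.47
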