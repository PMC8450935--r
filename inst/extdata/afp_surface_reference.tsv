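protein	eta_surf_IBS	eta_surf_NIBS
TisAFP6	0.056	0.057
PaAFP	0.033	0.053
ZaAFP	0.038	0.055
TisAFP8	0.032	0.054
CfAFP337	0.052	0.064
TmAFP	0.047	0.077
RiAFP	0.059	0.063
CfAFP501	0.040	0.069
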