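residue_name	atom_name	element	vdw_radius	charge
SOL	OW	O	0.158	-0.82
SOL	HW1	H	0	0.41
SOL	HW2	H	0	0.41
HOH	O	O	0.158	-0.82
HOH	H1	H	0	0.41
HOH	H2	H	0	0.41
HOH	OW	O	0.158	-0.82
WAT	O	O	0.158	-0.82
WAT	H1	H	0	0.41
WAT	H2	H	0	0.41
SPC	OW	O	0.158	-0.82
SPC	HW1	H	0	0.41
SPC	HW2	H	0	0.41
		H	0.110	0
		C	0.170	0
		N	0.155	0
		O	0.152	0
		S	0.180	0
		P	0.180	0
		F	0.147	0
		CL	0.175	0
		NA	0.227	0
		K	0.275	0
		MG	0.173	0
		CA	0.231	0
		ZN	0.139	0
		FE	0.156	0
		BR	0.185	0
		I	0.198	0
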