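toxin_resname	toxin_resno	isoform	channel_resname	channel_resno	kinds
LYS	15	Kv1.1	GLU	353	hbond,salt_bridge
LYS	18	Kv1.1	SER	354	hbond
LYS	18	Kv1.1	HIS	355	cation_pi
LYS	18	Kv1.2	GLN	353	hbond
GLN	12	Kv1.2	ASP	351	hbond
ASP	33	Kv1.1	ASP	377	repulsion
ASP	33	Kv1.2	ASP	375	repulsion
ASP	33	Kv1.3	ASP	399	repulsion
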