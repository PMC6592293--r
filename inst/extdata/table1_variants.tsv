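case_id	gene	protein_change	maf_percent	read_depth	assay	somatic_status
1	KRAS	p.G12V			PNA_CLAMP	cosmic_confirmed
2	KRAS	p.G12V			PNA_CLAMP	cosmic_confirmed
2	GNAS	p.R201C			PNA_CLAMP	cosmic_confirmed
3	KRAS	p.G12V			PNA_CLAMP	cosmic_confirmed
3	GNAS	p.R201C			PNA_CLAMP	cosmic_confirmed
4	KRAS	p.G12V			PNA_CLAMP	cosmic_confirmed
4	GNAS	p.R201H			PNA_CLAMP	cosmic_confirmed
5	KRAS	p.G12V			PNA_CLAMP	cosmic_confirmed
6	KRAS	p.G12R			PNA_CLAMP	cosmic_confirmed
7	KRAS	p.G12R			PNA_CLAMP	cosmic_confirmed
7	GNAS	p.R201H			PNA_CLAMP	cosmic_confirmed
8	KRAS	p.G12A			PNA_CLAMP	cosmic_confirmed
8	GNAS	p.R201H			PNA_CLAMP	cosmic_confirmed
9	KRAS	p.G12R			PNA_CLAMP	cosmic_confirmed
11	KRAS	p.G12V			PNA_CLAMP	cosmic_confirmed
11	GNAS	p.R201C			PNA_CLAMP	cosmic_confirmed
12	KRAS	p.Q61H			PNA_CLAMP	cosmic_confirmed
12	GNAS	p.R201H			PNA_CLAMP	cosmic_confirmed
13	KRAS	p.G12D			PNA_CLAMP	cosmic_confirmed
14	KRAS	p.G12D			PNA_CLAMP	cosmic_confirmed
14	GNAS	p.R201C			PNA_CLAMP	cosmic_confirmed
14	APC				NGS	cosmic_confirmed
15	KRAS	p.G12V			PNA_CLAMP	cosmic_confirmed
15	GNAS	p.R201C			PNA_CLAMP	cosmic_confirmed
15	CDKN2A				NGS	cosmic_confirmed
16	KRAS	p.G12A			PNA_CLAMP	cosmic_confirmed
16	KRAS	p.G12T			PNA_CLAMP	cosmic_confirmed
16	GNAS	p.R201C			PNA_CLAMP	cosmic_confirmed
16	GNAS	p.R201H			PNA_CLAMP	cosmic_confirmed
17	GNAS	p.R201C			PNA_CLAMP	cosmic_confirmed
18	KRAS	p.G12V			PNA_CLAMP	cosmic_confirmed
18	TP53				NGS	cosmic_confirmed
18	PIK3CA				NGS	cosmic_confirmed
19	BRAF				PNA_CLAMP	cosmic_confirmed
20	KRAS	p.Q61H			PNA_CLAMP	cosmic_confirmed
22	KRAS	p.G12D			PNA_CLAMP	cosmic_confirmed
23	KRAS	p.G12D			PNA_CLAMP	cosmic_confirmed
25	KRAS	p.G12D			PNA_CLAMP	cosmic_confirmed
25	TP53				NGS	cosmic_confirmed
26	KRAS	p.G12V			PNA_CLAMP	cosmic_confirmed
28	KRAS	p.G12D			PNA_CLAMP	cosmic_confirmed
29	KRAS	p.G12R			PNA_CLAMP	cosmic_confirmed
29	TP53				NGS	cosmic_confirmed
30	KRAS	p.G12V			PNA_CLAMP	cosmic_confirmed
30	TP53				NGS	cosmic_confirmed
30	SMAD4				NGS	cosmic_confirmed
31	KRAS	p.G12D			PNA_CLAMP	cosmic_confirmed
31	SMAD4				NGS	cosmic_confirmed
32	KRAS	p.G12D			PNA_CLAMP	cosmic_confirmed
32	RB1				NGS	cosmic_confirmed
32	SMAD4				NGS	cosmic_confirmed
32	PTEN				NGS	cosmic_confirmed
33	KRAS	p.G12D			PNA_CLAMP	cosmic_confirmed
33	TP53				NGS	cosmic_confirmed
34	GNAS	p.R201H			PNA_CLAMP	cosmic_confirmed
34	SMAD4				NGS	cosmic_confirmed
34	TP53				NGS	cosmic_confirmed
35	KRAS	p.Q61C			PNA_CLAMP	cosmic_confirmed
35	GNAS	p.R201C			PNA_CLAMP	cosmic_confirmed
35	TP53				NGS	cosmic_confirmed
35	CDKN2A				NGS	cosmic_confirmed
36	KRAS	p.G12D			PNA_CLAMP	cosmic_confirmed
36	GNAS	p.R201H			PNA_CLAMP	cosmic_confirmed
37	VHL				NGS	cosmic_confirmed
38	VHL				NGS	cosmic_confirmed
40	ATM				NGS	cosmic_confirmed
44	KRAS	p.G12D			PNA_CLAMP	cosmic_confirmed
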