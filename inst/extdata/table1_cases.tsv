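case_id	pathology_dx	dysplasia_grade	cytology	cea_ng_ml	amylase_u_l	cyst_size_mm	mural_nodule	viscosity	eus_impression	genes_tested	algorithm_label	molecular_label
1	IPMN	LG	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
2	IPMN	LG	A/S				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
3	IPMN	LG	A/S				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
4	IPMN	LG	ND				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
5	IPMN	LG	ND				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
6	IPMN	LG	A/S				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
7	IPMN	LG	A/S				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
8	IPMN	LG	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
9	IPMN	LG	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
10	IPMN	LG	ND				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	nmPCL
11	IPMN	LG	ND				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
12	IPMN	LG	ND				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
13	IPMN	MG	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
14	IPMN	MG	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
15	IPMN	MG	POS				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
16	IPMN	MG	ND				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
17	IPMN	MG	ND				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
18	IPMN	HG	A/S				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
19	IPMN	HG	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
20	MCN	LG	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
21	MCN	LG	ND				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	nmPCL
22	MCN	LG	A/S				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
23	MCN	LG	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
24	MCN	LG	ND				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	nmPCL
25	MCN	MG	A/S				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
26	MCN	MG	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
27	MCN	MG	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	nmPCL
28	MCN	MG	ND				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
29	PDAC	NA	POS				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
30	PDAC	NA	POS				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
31	PDAC	NA	POS				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
32	PDAC	NA	POS				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
33	PDAC	NA	POS				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
34	PDAC	NA	POS				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
35	PDAC	NA	POS				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
36	PDAC	NA	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
37	SCA	NA	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	nmPCL
38	SCA	NA	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	nmPCL	nmPCL
39	PNET	NA	A/S				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	nmPCL
40	PNET	NA	POS				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	nmPCL
41	PNET	NA	A/S				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	nmPCL
42	PSEUDOCYST	NA	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	nmPCL	nmPCL
43	PSEUDOCYST	NA	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	nmPCL	nmPCL
44	PSEUDOCYST	NA	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	mPCN	mPCN
45	PSEUDOCYST	NA	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	nmPCL	nmPCL
46	PSEUDOCYST	NA	NEG				unknown	unknown	unknown	KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM;RB1	nmPCL	nmPCL
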