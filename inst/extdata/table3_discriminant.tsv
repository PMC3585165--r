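rank	gene_symbol	gene_title	mitochondrial	muscle_specific	in_de_list
1	ACTN3	actinin, alpha 3	TRUE	TRUE	TRUE
2	PGAM2	phosphoglycerate mutase 2	FALSE	TRUE	TRUE
3	MYL3	myosin, light chain 3, alkali; ventricular, skeletal, slow	FALSE	TRUE	TRUE
4	MLF1	myeloid leukemia factor 1	FALSE	FALSE	TRUE
5	FBP2	fructose-1,6-bisphosphatase 2	TRUE	TRUE	TRUE
6	DBI	diazepam binding inhibitor	FALSE	FALSE	TRUE
7	ENO3	enolase 3	FALSE	TRUE	TRUE
8	PPP1R1A	protein phosphatase 1, regulatory (inhibitor) subunit 1A	FALSE	FALSE	TRUE
9	FABP3	fatty acid binding protein 3	FALSE	TRUE	TRUE
10	COX6A2	cytochrome c oxidase subunit VIa polypeptide 2	TRUE	FALSE	FALSE
11	MN1	meningioma	FALSE	FALSE	TRUE
12	FHL3	four and a half LIM domains 3	FALSE	TRUE	TRUE
13	FEZ2	fasciculation and elongation protein zeta 2	FALSE	FALSE	FALSE
14	TFRC	transferrin receptor (p90, CD71)	FALSE	TRUE	TRUE
15	LMOD1	leiomodin 1	FALSE	TRUE	TRUE
16	SEPW1	selenoprotein W	FALSE	FALSE	FALSE
17	TSPAN8	tetraspanin 8	FALSE	FALSE	TRUE
18	HRASLS	HRAS-like suppressor	TRUE	FALSE	TRUE
19	COX8A	cytochrome c oxidase subunit VIIIA	TRUE	FALSE	FALSE
20	GMPR	guanosine monophosphate reductase	FALSE	FALSE	FALSE
21	LMCD1	LIM and cysteine-rich domains 1	FALSE	FALSE	FALSE
22	NDUFA3	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex, 3, 9 kDa	TRUE	FALSE	FALSE
23	COX6B1	cytochrome c oxidase sub VIb polypeptide 1	TRUE	FALSE	FALSE
24	MYH2	myosin, heavy chain 2, skeletal muscle, adult	FALSE	TRUE	FALSE
25	ATP5J	ATP synthase, H+ transporting, mitochondrial Fo complex, subunit F6	FALSE	FALSE	FALSE
26	NDUFB3	NADH dehydrogenase 1 beta subcomplex, 3	TRUE	FALSE	FALSE
27	RPL3L	ribosomal protein L3-like	FALSE	FALSE	FALSE
28	C14orf2	chromosome 14 open reading frame 2	TRUE	FALSE	FALSE
29	NDUFB4	NADH dehydrogenase 1 beta subcomplex, 4,	TRUE	FALSE	FALSE
30	ART3	ADP-ribosyltransferase 3	FALSE	TRUE	FALSE
31	MYOM2	myomesin (M-protein) 2, 165 kDa	FALSE	TRUE	FALSE
32	COX6C	cytochrome c oxidase subunit VIc	TRUE	FALSE	FALSE
33	MKNK2	MAP kinase interacting serine/threonine kinase 2	TRUE	FALSE	FALSE
34	COX7C	cytochrome c oxidase subunit VIIc	TRUE	FALSE	FALSE
35	FKBP3	FK506 binding protein 3, 25 kDa	FALSE	FALSE	FALSE
36	G0S2	G0/G1switch 2	FALSE	FALSE	FALSE
37	COX7A1	cytochrome c oxidase subunit VIIa polypeptide 1	TRUE	FALSE	FALSE
38	COX5B	cytochrome c oxidase subunit Vb	TRUE	FALSE	FALSE
39	MEFV	Mediterranean fever	FALSE	TRUE	FALSE
40	NDUFAB1	NADH dehydrogenase 1, alpha/beta subcomplex	TRUE	FALSE	FALSE
41	MRPL33	mitochondrial ribosomal protein L33	TRUE	FALSE	FALSE
42	NDUFA6	NADH dehydrogenase 1 alpha subcomplex 6	TRUE	FALSE	FALSE
43	NDUFA4	NADH dehydrogenase1 alpha subcomplex, 4	TRUE	FALSE	FALSE
44	ATP5G1	ATP synthase, H+ transporting, mitochondrial Fo complex, subunit C1 (subunit 9)	FALSE	FALSE	FALSE
45	HOXA10	homeobox A10	TRUE	FALSE	FALSE
46	MYOT	myotilin	FALSE	TRUE	FALSE
47	PPP1R3C	protein phosphatase 1, regulatory (inhibitor) subunit 3C	FALSE	FALSE	FALSE
48	ATPIF1	ATPase inhibitory factor 1	FALSE	FALSE	FALSE
49	MGST3	microsomal glutathione S-transferase 3	TRUE	FALSE	FALSE
50	VEGFA	vascular endothelial growth factor A	FALSE	FALSE	FALSE
51	MAGED1	melanoma antigen family D, 1	FALSE	TRUE	TRUE
52	HPRT1	hypoxanthine phosphoribosyltransferase 1	TRUE	FALSE	TRUE
53			FALSE	FALSE	FALSE
54	ABCA8	ATP-binding cassette, sub-family A (ABC1), member 8	FALSE	FALSE	TRUE
55	SOX4	SRY (sex determining region Y)-box 4	TRUE	FALSE	TRUE
56	ATXN1	ataxin 1	TRUE	FALSE	TRUE
57	FBLN1	fibulin 1	TRUE	FALSE	TRUE
58	PSAP	prosaposin	FALSE	FALSE	TRUE
59	NDRG2	NDRG family member 2	FALSE	FALSE	FALSE
60	COL1A2	collagen, type I, alpha 2	FALSE	FALSE	TRUE
61	SPARC	secreted protein, acidic, cysteine-rich (osteonectin)	FALSE	FALSE	TRUE
62	CHRNB1	cholinergic receptor, nicotinic, beta 1 (muscle)	FALSE	TRUE	TRUE
63	ZFP36L1	zinc finger protein 36, C3H type-like 1	TRUE	FALSE	TRUE
64	CCNG2	cyclin G2	TRUE	FALSE	TRUE
65	MTHFD2	methylenetetrahydrofolate dehydrogenase	FALSE	FALSE	TRUE
66	ZFP36L2	zinc finger protein 36, C3H type-like 2	TRUE	FALSE	TRUE
67	CALM1	calmodulin 1 (phosphorylase kinase, delta)	TRUE	FALSE	TRUE
68	CYP26B1	cytochrome P450, family 26, subfamily B, polypeptide 1	FALSE	FALSE	TRUE
69	CCT2	chaperonin containing TCP1, subunit 2 (beta)	FALSE	FALSE	TRUE
70	RYR3	ryanodine receptor 3	FALSE	FALSE	TRUE
71	COL3A1	collagen, type III, alpha 1	TRUE	FALSE	TRUE
72	NRAP	nebulin-related anchoring protein	FALSE	TRUE	FALSE
73	PDGFC	platelet derived growth factor C	FALSE	FALSE	TRUE
74	ETS2	v-ets erythroblastosis virus E26 oncogene homolog 2	FALSE	FALSE	TRUE
75	VIM	vimentin	FALSE	FALSE	TRUE
76	PRNP	prion protein	FALSE	FALSE	TRUE
77	DMPK	dystrophia myotonica-protein kinase	FALSE	TRUE	TRUE
78	ADAMTS1	ADAM metallopeptidase with thrombospondin type 1 motif, 1	FALSE	FALSE	TRUE
79	SLC7A6	solute carrier family 7 (cationic amino acid transporter, y+ system), member 6	TRUE	FALSE	TRUE
80	RHOB	ras homolog gene family, member B	TRUE	FALSE	TRUE
81	ARPP21	cAMP-regulated phosphoprotein, 21 kDa	FALSE	FALSE	TRUE
82	COL1A1	collagen, type I, alpha 1	FALSE	FALSE	TRUE
83	EZR	ezrin	FALSE	TRUE	TRUE
84	HDAC4	histone deacetylase 4	FALSE	TRUE	TRUE
85	CYR61	cysteine-rich, angiogenic inducer, 61	FALSE	FALSE	TRUE
86	C10orf116	chromosome 10 open reading frame 116	TRUE	FALSE	TRUE
87	ANXA1	annexin A1	FALSE	TRUE	TRUE
88	MYL5	myosin, light chain 5, regulatory	FALSE	TRUE	TRUE
89	EEF1A1	eukaryotic translation elongation factor 1 alpha 1	FALSE	TRUE	TRUE
90	RRAD	Ras-related associated with diabetes	FALSE	FALSE	TRUE
91	EEF1A1	eukaryotic translation elongation factor 1 alpha 1	FALSE	FALSE	TRUE
92	MYH3	myosin, heavy chain 3, skeletal muscle, embryonic	FALSE	TRUE	TRUE
93	CDKN1A	cyclin-dependent kinase inhibitor 1A (p21, Cip1)	FALSE	FALSE	TRUE
94	ACTC1	actin, alpha, cardiac muscle 1	FALSE	TRUE	TRUE
95	MYH8	myosin, heavy chain 8, skeletal muscle, perinatal	FALSE	TRUE	TRUE
96	MYH8	myosin, heavy chain 8, skeletal muscle, perinatal	FALSE	TRUE	TRUE
97	CDC42EP3	CDC42 effector protein (Rho GTPase binding) 3	FALSE	TRUE	TRUE
98	NNMT	nicotinamide N-methyltransferase	FALSE	FALSE	TRUE
99	GADD45A	growth arrest and DNA-damage-inducible, alpha	FALSE	FALSE	TRUE
100	CHRNA1	cholinergic receptor, nicotinic, alpha 1 (muscle)	FALSE	TRUE	TRUE
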