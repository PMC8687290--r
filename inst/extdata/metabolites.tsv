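id	abbreviation	name	carbon_count	biomass_glucose	biomass_glucose_glycerol
1	NAD	nicotinamide adenine dinucleotide	21	0.8	0.8
2	NADP	nicotinamide adenine dinucleotide phosphate	21	0.2	0.2
3	ATP	adenosine triphosphate	10	-2.5	-2.5
4	Ser	serine	3	-0.03	-0.03
5	3-PG	3-phosphoglycerate	3	0	0
6	2-PG	2-phosphoglycerate	3	0	0
7	PEP	phosphoenolpyruvate	3	-0.05	-0.05
8	OAA	oxaloacetate	4	-0.2	-0.2
9	Mal	malate	4	0	0
10	Ac-CoA	acetyl-CoA	23	-0.2	-0.2
11	Pyr	pyruvate	3	-0.2	-0.2
12	CoA	coenzyme A	21	0.23	0.23
13	Cit	citrate	6	0	0
14	Cis-acon	cis-aconitate	6	0	0
15	Icit	isocitrate	6	0	0
16	a-KG	alpha-ketoglutarate	5	-0.07	-0.07
17	Succ-CoA	succinyl-CoA	25	-0.03	-0.03
18	Succ	succinate	4	-0.03	-0.03
19	Fum	fumarate	4	0	0
20	FAD	flavin adenine dinucleotide	27	0	0
21	G-6-P	glucose 6-phosphate	6	0	0
22	F-6-P	fructose 6-phosphate	6	-0.07	-0.07
23	FBP	fructose 1,6-biphosphate	6	0	0
24	DHAP	dihydroxyacetone phosphate	3	0	0
25	TP	glyceraldehyde 3-phosphate	3	-0.01	-0.01
26	1,3-BPG	1,3-biphosphoglycerate	3	0	0
27	6-PG	6-phosphogluconate	6	0	0
28	R-5-P	ribose 5-phosphate	5	-0.05	-0.05
29	Ru-5-P	ribulose 5-phosphate	5	0	0
30	Xu-5-P	xylulose 5-phosphate	5	0	0
31	S-7-P	sedoheptulose-7-phosphate	7	0	0
32	E-4-P	erythrose-4-phosphate	4	-0.02	-0.02
33	Glu	glutamate	5	-0.07	-0.07
34	Q	ubiquinone	49	0	0
35	Cyt-Cox	cytochrome-c (oxidised)	0	0	0
36	NADH	nicotinamide adenine dinucleotide (reduced)	21	-0.8	-0.8
37	NADPH	nicotinamide adenine dinucleotide phosphate (reduced)	21	-0.2	-0.2
38	ADP	adenosine diphosphate	10	2.5	2.5
39	FADH2	flavin adenine dinucleotide (reduced)	27	0	0
40	QH2	ubiquinol	49	0	0
41	Cyt-Cred	cytochrome-c (reduced)	0	0	0
42	CO2	carbon dioxide	1	0	0
43	NH4	ammonium	0	0.06	0.1
44	Pi	phosphate	0	0.19996	0.2
45	H	membrane-bound proton	0	0	0
46	glycrol-3P	D-glycerol-3-phosphate	3	0	0
47	glycerol	glycerol	3	0	0
48	DAHP	3-deoxy-D-arabino-heptulosonate-7-phosphate	7	0	0
49	DHQ	3-dehydroquinate	7	0	0
50	DHS	3-dehydroshikimate	7	0	0
51	shikimate	shikimate	7	0	0
52	shikimate-3P	shikimate 3-phosphate	7	0	0
53	EPSP	5-enolpyruvyl-shikimate 3-phosphate	10	0	0
54	chorismate	chorismate	10	0	0
55	4HB	4-hydroxybenzoic acid	7	0	0
56	G-4HB	3-geranyl-4-hydroxybenzoic acid	17	0	0
57	XiaB	xiamenmycin B	17	0	0
58	XiaA	xiamenmycin A	21	-0.05	-0.07
59	GPP	geranyl pyrophosphate	10	0	0
60	Thr	L-threonine	4	0	0
61	AMP	adenosine monophosphate	10	0	0
62	DXP	1-deoxy-D-xylulose 5-phosphate	5	0	0
63	MEP	2-C-methyl-D-erythritol 4-phosphate	5	0	0
64	CDP-ME	4-(cytidine 5'-diphospho)-2-C-methyl-D-erythritol	14	0	0
65	CDP-MEP	2-phospho-4-(cytidine 5'-diphospho)-2-C-methyl-D-erythritol	14	0	0
66	ME-CPP	2-C-methyl-D-erythritol 2,4-cyclodiphosphate	5	0	0
67	HMBPP	1-hydroxy-2-methyl-2-(E)-butenyl 4-diphosphate	5	0	0
68	IPP	isopentenyl diphosphate	5	0	0
69	DMAPP	dimethylallyl diphosphate	5	0	0
70	CTP	cytidine-triphosphate	9	0	0
71	CMP	cytidine-5'-monophosphate	9	0	0
72	CDP	cytidine-diphosphate	9	0	0
73	ox-FD	oxidised ferredoxin	0	0	0
74	re-FD	reduced ferredoxin	0	0	0
75	Asp	L-aspartate	4	0	0
76	Asp-4P	L-aspartate 4-phosphate	4	0	0
77	Asp-SA	L-aspartate-semi-aldehyde	4	0	0
78	HSER	L-homoserine	4	0	0
79	PSER	O-phospho-L-homoserine	4	0	0
80	Glc	glucose	6	0	0
81	Acetate	acetate	2	0	0
82	PHP	3-phosphohydroxypyruvate	3	0	0
83	3Pser	3-phosphoserine	3	0	0
84	Gln	glutamine	5	0	0
85	GTP	guanosine triphosphate	10	0	0
86	GDP	guanosine diphosphate	10	0	0
1000	external	external network	0	-0.00057	-2.75e-14
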