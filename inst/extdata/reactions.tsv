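id	equation	kind	flux_glucose	flux_glucose_glycerol
1	2-PG <-> 3-PG	internal	-0.82659	-0.91367
2	2-PG <-> PEP	internal	0.82659	0.91367
3	PEP + CO2 <-> OAA + Pi	internal	0.54279	0.5468
4	OAA + NADH <-> Mal + NAD	internal	-0.07568	-0.0712
5	Pyr + CoA + NAD -> Ac-CoA + CO2 + NADH	internal	0.44552	0.43047
6	Ac-CoA + OAA -> Cit + CoA	internal	0.24442	0.22959
7	Cis-acon <-> Cit	internal	-0.24442	-0.22959
8	Icit <-> Cis-acon	internal	-0.24442	-0.22959
9	Icit + NADP -> a-KG + NADPH + CO2	internal	0.24442	0.22959
10	a-KG + 2 ox-FD + CoA -> Succ-CoA + CO2 + 2 re-FD	internal	0.24442	0.22959
11	Succ + ATP + CoA <-> Succ-CoA + Pi + ADP	internal	-0.21442	-0.19959
12	Fum + FADH2 <-> Succ + FAD	internal	-0.18442	-0.16959
13	Fum <-> Mal	internal	0.18442	0.16959
14	G-6-P <-> F-6-P	internal	0.57208	0.46316
15	FBP -> F-6-P + Pi	internal	0.027647	0.036677
16	FBP <-> DHAP + TP	internal	0.63255	0.48471
17	TP <-> DHAP	internal	-0.63274	-0.91497
18	TP + Pi + NAD <-> 1,3-BPG + NADH	internal	1.1855	1.2505
19	3-PG + ATP <-> 1,3-BPG + ADP	internal	-1.1855	-1.2505
20	OAA + GTP -> PEP + GDP + CO2	internal	0.12405	0.11841
21	PEP + ADP <-> Pyr + ATP	internal	-0.4302	-0.44886
22	Mal + NAD -> Pyr + CO2 + NADH	internal	0.10875	0.098384
23	G-6-P + NADP -> 6-PG + NADPH	internal	0.2807	0.23234
24	6-PG + NADP -> Ru-5-P + CO2 + NADPH	internal	0.2807	0.23234
25	R-5-P <-> Ru-5-P	internal	-0.15023	-0.14078
26	Ru-5-P <-> Xu-5-P	internal	0.13046	0.091559
27	Xu-5-P + R-5-P <-> S-7-P + TP	internal	0.10023	0.090779
28	S-7-P + TP <-> F-6-P + E-4-P	internal	0.10023	0.090779
29	Xu-5-P + E-4-P <-> F-6-P + TP	internal	0.030232	0.000779
30	Glu + NADP <-> NH4 + a-KG + NADPH	internal	-0.51131	-0.51318
31	NADH + Q -> NAD + QH2 + 2 H	internal	1.3859	1.5046
32	QH2 + 2 Cyt-Cox -> Q + 2 Cyt-Cred	internal	1.5703	1.6742
33	FADH2 + Q -> FAD + QH2	internal	0.18442	0.16959
34	ATP <- ADP + 2 H + Pi	internal	-2.3392	-2.5443
35	Cyt-Cred -> Cyt-Cox + H	internal	3.1406	3.3484
36	NADH + NADP + H <-> NADPH + NAD	internal	1.0896	1.1795
37	Ser -> Pyr + NH4	internal	0.32892	0.30679
38	glycrol-3P + NAD -> DHAP + NADH	internal	0.000189	0.43026
39	glycerol + ATP -> glycrol-3P + ADP	internal	0.000151	0.43026
40	PEP + E-4-P -> DAHP + Pi	internal	0.05	0.07
41	DAHP -> DHQ + Pi	internal	0.05	0.07
42	DHQ <-> DHS	internal	0.05	0.07
43	DHS + NADPH <-> shikimate + NADP	internal	0.057585	0.024537
44	ATP + shikimate <-> ADP + shikimate-3P	internal	0.05	0.07
45	PEP + shikimate-3P <-> Pi + EPSP	internal	0.05	0.07
46	EPSP -> chorismate + Pi	internal	0.05	0.07
47	chorismate + Gln <-> 4HB + Pyr + Glu	internal	0.05	0.07
48	GPP + 4HB <-> G-4HB + 2 Pi	internal	0.05	0.07
49	G-4HB + NADPH <-> XiaB + NADP	internal	0.05	0.07
50	XiaB + Thr + ATP <-> XiaA + AMP + 2 Pi	internal	0.05	0.07
51	ATP + AMP <-> 2 ADP	internal	-0.63914	-0.67503
52	TP + Pyr -> DXP + CO2	internal	0.1	0.14
53	DXP + NADPH <-> MEP + NADP	internal	0.1	0.14
54	MEP + CTP <-> CDP-ME + 2 Pi	internal	0.1	0.14
55	CDP-ME + ATP <-> CDP-MEP + ADP	internal	0.1	0.14
56	CDP-MEP <-> ME-CPP + CMP	internal	0.1	0.14
57	ME-CPP + 2 re-FD <-> HMBPP + 2 ox-FD	internal	0.1	0.14
58	HMBPP + NADH <-> IPP + NAD	internal	-0.47853	-0.41127
59	IPP <-> DMAPP	internal	0.05	0.07
60	DMAPP + IPP <-> GPP + 2 Pi	internal	0.05	0.07
61	CMP + ATP <-> CDP + ADP	internal	0.1	0.14
62	CDP + ATP <-> CTP + ADP	internal	0.1	0.14
63	HMBPP + NADPH <-> IPP + NADP	internal	0.57853	0.55127
64	shikimate + NAD <-> DHS + NADH	internal	0.007586	-0.04546
65	OAA + NH4 + Succ <-> Asp + Fum	internal	0.05	0.07
66	Asp + ATP <-> Asp-4P + ADP	internal	0.05	0.07
67	Asp-4P + NADPH <-> Asp-SA + NADP + Pi	internal	0.05	0.07
68	Asp-SA + NADH <-> HSER + NAD	internal	-0.47041	-0.41116
69	HSER + ATP <-> PSER + ADP	internal	0.05	0.07
70	PSER -> Thr + Pi	internal	0.05	0.07
71	Asp-SA + NADPH <-> HSER + NADP	internal	0.52041	0.48116
72	F-6-P + ATP -> FBP + ADP	internal	0.66019	0.52139
73	Pyr + ATP <-> PEP + AMP + Pi	internal	-0.68804	-0.74415
74	ATP + Glc <-> ADP + G-6-P	internal	0.85278	0.69549
75	2 re-FD + NAD + H <-> 2 ox-FD + NADH	internal	0.14442	0.089588
76	Ac-CoA + 2 Pi + AMP <-> Acetate + ATP + CoA	internal	0.001093	0.000877
77	3-PG + NAD <-> PHP + NADH	internal	0.35892	0.33679
78	PHP + Glu -> a-KG + 3Pser	internal	0.35892	0.33679
79	3Pser -> Ser + Pi	internal	0.35892	0.33679
80	a-KG + Gln + NADPH <-> 2 Glu + NADP	internal	-0.17238	-0.17639
81	Glu + NH4 <-> Gln	internal	-0.12238	-0.10639
82	ATP + GDP <-> ADP + GTP	internal	0.12405	0.11841
1001	ATP -> ADP + Pi	maintenance	2.5	2.5
1002	NADPH -> NADP	maintenance	0.2	0.2
1003	NADH -> NAD	maintenance	0.8	0.8
1004	external <- CO2	exchange	-1.0051	-0.93198
1005	external <- Ac-CoA	exchange	-0.2	-0.2
1006	external <- Pyr	exchange	-0.2	-0.2
1007	external <- OAA	exchange	-0.2	-0.2
1008	external <- a-KG	exchange	-0.07	-0.07
1009	external <- Glu	exchange	0.07	0.07
1010	external <- F-6-P	exchange	-0.07	-0.07
1011	external <- PEP	exchange	-0.05	-0.05
1012	external <- R-5-P	exchange	-0.05	-0.05
1013	external <- Succ-CoA	exchange	-0.03	-0.03
1014	external <- Ser	exchange	-0.03	-0.03
1015	external <- E-4-P	exchange	-0.02	-0.02
1016	external <- TP	exchange	-0.01	-0.01
1017	external -> Glc	exchange	0.85278	0.69549
1018	external <- XiaA	exchange	-0.05	-0.07
1019	external <- Acetate	exchange	-0.00109	-0.00088
1020	external <- Succ	exchange	-0.03	-0.03
1021	external -> glycerol	exchange	0	0.43026
1022	external -> 4HB	exchange	0	0
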