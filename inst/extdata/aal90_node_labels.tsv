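node_index	label	hemisphere	lobe
0	PreCG.L	L	frontal
1	SFGdor.L	L	frontal
2	ORBsup.L	L	frontal
3	MFG.L	L	frontal
4	ORBmid.L	L	frontal
5	IFGoperc.L	L	frontal
6	IFGtriang.L	L	frontal
7	ORBinf.L	L	frontal
8	ROL.L	L	frontal
9	SMA.L	L	frontal
10	OLF.L	L	frontal
11	SFGmed.L	L	frontal
12	ORBsupmed.L	L	frontal
13	REC.L	L	frontal
14	INS.L	L	subcortical
15	ACG.L	L	frontal
16	DCG.L	L	frontal
17	PCG.L	L	parietal
18	HIP.L	L	medial-temporal
19	PHG.L	L	medial-temporal
20	AMYG.L	L	medial-temporal
21	CAL.L	L	occipital
22	CUN.L	L	occipital
23	LING.L	L	occipital
24	SOG.L	L	occipital
25	MOG.L	L	occipital
26	IOG.L	L	occipital
27	FFG.L	L	medial-temporal
28	PoCG.L	L	parietal
29	SPG.L	L	parietal
30	IPL.L	L	parietal
31	SMG.L	L	parietal
32	ANG.L	L	parietal
33	PCUN.L	L	parietal
34	PCL.L	L	frontal
35	CAU.L	L	subcortical
36	PUT.L	L	subcortical
37	PAL.L	L	subcortical
38	THA.L	L	subcortical
39	HES.L	L	temporal
40	STG.L	L	temporal
41	TPOsup.L	L	temporal
42	MTG.L	L	temporal
43	TPOmid.L	L	temporal
44	ITG.L	L	temporal
45	PreCG.R	R	frontal
46	SFGdor.R	R	frontal
47	ORBsup.R	R	frontal
48	MFG.R	R	frontal
49	ORBmid.R	R	frontal
50	IFGoperc.R	R	frontal
51	IFGtriang.R	R	frontal
52	ORBinf.R	R	frontal
53	ROL.R	R	frontal
54	SMA.R	R	frontal
55	OLF.R	R	frontal
56	SFGmed.R	R	frontal
57	ORBsupmed.R	R	frontal
58	REC.R	R	frontal
59	INS.R	R	subcortical
60	ACG.R	R	frontal
61	DCG.R	R	frontal
62	PCG.R	R	parietal
63	HIP.R	R	medial-temporal
64	PHG.R	R	medial-temporal
65	AMYG.R	R	medial-temporal
66	CAL.R	R	occipital
67	CUN.R	R	occipital
68	LING.R	R	occipital
69	SOG.R	R	occipital
70	MOG.R	R	occipital
71	IOG.R	R	occipital
72	FFG.R	R	medial-temporal
73	PoCG.R	R	parietal
74	SPG.R	R	parietal
75	IPL.R	R	parietal
76	SMG.R	R	parietal
77	ANG.R	R	parietal
78	PCUN.R	R	parietal
79	PCL.R	R	frontal
80	CAU.R	R	subcortical
81	PUT.R	R	subcortical
82	PAL.R	R	subcortical
83	THA.R	R	subcortical
84	HES.R	R	temporal
85	STG.R	R	temporal
86	TPOsup.R	R	temporal
87	MTG.R	R	temporal
88	TPOmid.R	R	temporal
89	ITG.R	R	temporal
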