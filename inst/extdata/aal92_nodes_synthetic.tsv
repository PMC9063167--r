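index	name	x	y	z	is_seed
0	Precentral_L	-39	-6	51	FALSE
1	Precentral_R	41	-8	52	FALSE
2	Frontal_Sup_L	-18	35	42	TRUE
3	Frontal_Sup_R	22	31	44	FALSE
4	Frontal_Sup_Orb_L	-17	47	-13	FALSE
5	Frontal_Sup_Orb_R	18	48	-14	FALSE
6	Frontal_Mid_L	-33	33	35	FALSE
7	Frontal_Mid_R	38	33	34	FALSE
8	Frontal_Mid_Orb_L	-31	50	-10	TRUE
9	Frontal_Mid_Orb_R	33	53	-11	FALSE
10	Frontal_Inf_Oper_L	-48	13	19	TRUE
11	Frontal_Inf_Oper_R	50	15	21	FALSE
12	Frontal_Inf_Tri_L	-46	30	14	FALSE
13	Frontal_Inf_Tri_R	50	30	14	FALSE
14	Frontal_Inf_Orb_L	-36	31	-12	FALSE
15	Frontal_Inf_Orb_R	41	32	-12	FALSE
16	Rolandic_Oper_L	-47	-8	14	FALSE
17	Rolandic_Oper_R	53	-6	15	FALSE
18	Supp_Motor_Area_L	-5	5	61	TRUE
19	Supp_Motor_Area_R	9	0	62	FALSE
20	Olfactory_L	-8	15	-11	FALSE
21	Olfactory_R	10	16	-11	FALSE
22	Frontal_Sup_Medial_L	-5	49	31	FALSE
23	Frontal_Sup_Medial_R	9	51	30	FALSE
24	Frontal_Med_Orb_L	-5	54	-7	FALSE
25	Frontal_Med_Orb_R	8	52	-7	FALSE
26	Rectus_L	-5	37	-18	FALSE
27	Rectus_R	8	36	-18	FALSE
28	Insula_L	-35	7	3	TRUE
29	Insula_R	39	6	2	FALSE
30	Cingulum_Ant_L	-4	35	14	FALSE
31	Cingulum_Ant_R	8	37	16	FALSE
32	Cingulum_Mid_L	-5	-15	42	FALSE
33	Cingulum_Mid_R	8	-9	40	TRUE
34	Cingulum_Post_L	-5	-43	25	FALSE
35	Cingulum_Post_R	7	-42	22	FALSE
36	Hippocampus_L	-25	-21	-10	FALSE
37	Hippocampus_R	29	-20	-10	FALSE
38	ParaHippocampal_L	-21	-16	-21	FALSE
39	ParaHippocampal_R	25	-15	-20	FALSE
40	Amygdala_L	-23	-1	-17	FALSE
41	Amygdala_R	27	1	-18	FALSE
42	Calcarine_L	-7	-79	6	FALSE
43	Calcarine_R	16	-73	9	FALSE
44	Cuneus_L	-6	-80	27	FALSE
45	Cuneus_R	14	-79	28	FALSE
46	Lingual_L	-15	-68	-5	FALSE
47	Lingual_R	16	-67	-4	FALSE
48	Occipital_Sup_L	-17	-84	28	FALSE
49	Occipital_Sup_R	24	-81	31	FALSE
50	Occipital_Mid_L	-32	-81	16	FALSE
51	Occipital_Mid_R	37	-80	19	FALSE
52	Occipital_Inf_L	-36	-78	-8	FALSE
53	Occipital_Inf_R	38	-82	-8	FALSE
54	Fusiform_L	-31	-40	-20	FALSE
55	Fusiform_R	34	-39	-20	FALSE
56	Postcentral_L	-42	-23	49	FALSE
57	Postcentral_R	41	-25	53	FALSE
58	Parietal_Sup_L	-23	-60	59	FALSE
59	Parietal_Sup_R	26	-59	62	FALSE
60	Parietal_Inf_L	-43	-46	47	FALSE
61	Parietal_Inf_R	46	-46	50	FALSE
62	SupraMarginal_L	-56	-34	30	FALSE
63	SupraMarginal_R	58	-32	34	FALSE
64	Angular_L	-44	-61	36	FALSE
65	Angular_R	46	-60	39	FALSE
66	Precuneus_L	-7	-56	48	TRUE
67	Precuneus_R	10	-56	44	FALSE
68	Paracentral_Lobule_L	-8	-25	70	FALSE
69	Paracentral_Lobule_R	7	-32	68	FALSE
70	Caudate_L	-11	11	9	TRUE
71	Caudate_R	15	12	9	FALSE
72	Putamen_L	-24	4	2	TRUE
73	Putamen_R	28	5	2	TRUE
74	Pallidum_L	-18	0	0	FALSE
75	Pallidum_R	21	0	0	FALSE
76	Thalamus_L	-11	-18	8	TRUE
77	Thalamus_R	13	-18	8	FALSE
78	Heschl_L	-42	-19	10	FALSE
79	Heschl_R	46	-17	10	FALSE
80	Temporal_Sup_L	-53	-21	7	FALSE
81	Temporal_Sup_R	58	-22	7	FALSE
82	Temporal_Pole_Sup_L	-40	15	-20	FALSE
83	Temporal_Pole_Sup_R	48	15	-17	FALSE
84	Temporal_Mid_L	-56	-34	-2	FALSE
85	Temporal_Mid_R	57	-37	-1	FALSE
86	Temporal_Pole_Mid_L	-36	15	-34	FALSE
87	Temporal_Pole_Mid_R	44	15	-32	TRUE
88	Temporal_Inf_L	-50	-28	-23	FALSE
89	Temporal_Inf_R	54	-31	-22	FALSE
90	Accumbens_L	-9	11	-7	TRUE
91	Accumbens_R	9	11	-7	FALSE
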