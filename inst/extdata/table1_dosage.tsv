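gene	te_fold_change	p_adj	protein_len_aa	clip_target	haplo_score	triplo_score
PRR12	0.51	0.0E+00	2035	TRUE	n/a	n/a
KMT2A	0.58	9.0E-05	3966	TRUE	3	0
HIVEP3	0.58	4.7E-04	2348	TRUE	1	0
SHANK1	0.59	0.0E+00	2167	TRUE	1	0
SETD1B	0.59	1.4E-03	1985	FALSE	n/a	n/a
KMT2C	0.61	4.0E-08	4904	TRUE	3	0
SPEN	0.63	2.7E-07	3620	TRUE	1	0
MED13L	0.63	4.8E-08	2207	TRUE	3	1
TCF20	0.64	7.1E-07	1987	TRUE	3	0
SCAF4	0.64	6.1E-04	1209	FALSE	n/a	n/a
AHDC1	0.65	2.2E-07	1594	TRUE	3	0
SRCAP	0.65	6.2E-07	3271	FALSE	1	0
CIC	0.66	5.4E-07	1604	TRUE	2	0
KDM3B	0.66	1.3E-06	1762	FALSE	n/a	n/a
CNOT3	0.66	5.0E-03	751	FALSE	0	0
MAP1A	0.67	0.0E+00	2776	TRUE	n/a	n/a
SHANK2	0.67	5.9E-08	1472	TRUE	2	0
RIMS1	0.67	9.7E-07	1190	FALSE	1	0
AUTS2	0.67	8.0E-06	1261	TRUE	3	0
RERE	0.68	1.0E-03	1558	TRUE	n/a	n/a
SYN1	0.68	1.2E-06	670	TRUE	2	0
HECTD4	0.68	0.0E+00	4418	FALSE	n/a	n/a
LRP1	0.69	0.0E+00	4545	TRUE	n/a	n/a
CAMK2A	0.69	3.0E-04	478	TRUE	1	0
CREBBP	0.69	1.1E-06	2441	TRUE	3	0
NOVA2	0.70	2.6E-03	492	FALSE	n/a	n/a
CHD8	0.70	2.7E-05	2582	TRUE	3	0
SHANK3	0.71	5.4E-03	1805	TRUE	3	0
ARID2	0.71	7.3E-04	1828	TRUE	3	0
ASH1L	0.71	2.9E-09	2958	TRUE	3	0
IQSEC2	0.71	1.3E-05	1479	TRUE	3	0
ZC3H4	0.72	3.6E-03	1255	TRUE	n/a	n/a
SON	0.72	5.2E-04	2444	TRUE	3	0
GRIK5	0.72	5.6E-03	979	TRUE	n/a	n/a
CACNA1A	0.72	1.6E-05	2327	TRUE	3	0
KIF5C	0.73	1.4E-10	956	TRUE	n/a	n/a
HUWE1	0.73	6.6E-10	4378	TRUE	0	0
ZMIZ1	0.74	1.5E-03	1066	TRUE	n/a	n/a
AKAP9	0.74	1.2E-03	3779	TRUE	n/a	n/a
NCOR1	0.74	4.1E-07	2454	TRUE	n/a	n/a
ARID1B	0.75	1.8E-04	2244	TRUE	3	0
AGO2	0.76	1.2E-03	860	FALSE	n/a	n/a
MYT1L	0.77	6.6E-03	1185	TRUE	3	0
FOXG1	0.78	8.6E-03	481	FALSE	3	0
MECP2	0.78	9.5E-03	484	FALSE	n/a	n/a
WDFY3	0.78	6.5E-06	3508	TRUE	n/a	n/a
VAMP2	0.78	6.7E-05	116	TRUE	n/a	n/a
NSD1	0.79	4.3E-03	2691	TRUE	3	0
CHD3	0.79	4.8E-04	2055	TRUE	n/a	n/a
EP400	0.80	8.2E-04	2999	TRUE	n/a	n/a
INTS1	0.80	5.2E-03	2222	TRUE	n/a	n/a
PHF3	0.80	2.7E-03	2025	FALSE	1	0
YWHAG	0.80	5.8E-04	247	TRUE	n/a	n/a
SLC12A5	0.81	5.0E-03	1138	TRUE	n/a	n/a
CTNND2	0.81	2.3E-04	1221	TRUE	2	0
SATB1	0.82	7.4E-03	764	FALSE	n/a	n/a
TRRAP	0.82	2.0E-04	3847	TRUE	1	0
NFIX	0.82	5.5E-04	433	TRUE	n/a	n/a
SYNE1	0.82	4.1E-03	1431	TRUE	n/a	n/a
TANC2	0.83	7.6E-03	1994	TRUE	n/a	n/a
ATP2B2	0.83	5.5E-04	1198	TRUE	n/a	n/a
ILF2	1.25	9.5E-03	390	FALSE	n/a	n/a
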