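study_id	author	year	ethnicity	snp	case_wtwt	case_varwt	case_varvar	ctrl_wtwt	ctrl_varwt	ctrl_varvar	n_cases	n_controls	laplace_applied	duplicate_subjects_of	mean_age_case	mean_age_control	sex_ratio_m_to_f	males_only	quality_score
matsushita_2004	Matsushita	2004	Asian	rs6265	141	176	60	106	162	68	377	336	FALSE	.	49.9	50.7	.	TRUE	8
shin_2010	Shin	2010	Asian	rs6265	8	41	19	61	127	44	68	232	FALSE	.	75.2	75.2	.	TRUE	8
su_2011_rs6265	Su	2011	Asian	rs6265	175	250	123	101	148	63	548	312	FALSE	.	45.4	44.8	.	TRUE	7
su_2011_rs16917204	Su	2011	Asian	rs16917204	252	222	74	137	128	47	548	312	FALSE	su_2011_rs6265	45.4	44.8	.	TRUE	7
tsai_2005	Tsai	2005	Asian	rs6265	25	63	22	29	85	35	110	149	FALSE	.	36.1	35.7	.	TRUE	7
mo_2021	Mo	2021	Asian	rs6265	17	33	9	8	20	9	59	37	FALSE	.	44	38	.	.	5
berent_2020	Berent	2020	Caucasian	rs6265	117	58	1	94	30	3	176	127	TRUE	.	43.4	39.4	3.15	FALSE	8
benzerouk_2013	Benzerouk	2013	Caucasian	rs6265	30	14	2	47	30	5	46	82	FALSE	.	36.2	34.8	0.31	FALSE	5
cheah_2014_rs6265	Cheah	2014	Caucasian	rs6265	22	18	2	64	33	1	42	98	FALSE	.	40.7	45.0	1.33	FALSE	8
cheah_2014_rs7103411	Cheah	2014	Caucasian	rs7103411	20	19	2	66	32	2	41	100	FALSE	.	40.7	45.0	1.33	FALSE	8
grzywacz_2010	Grzywacz	2010	Caucasian	rs6265	91	46	1	107	42	4	138	153	TRUE	.	39.0	37.0	6.9	FALSE	7
liu_2005	Liu	2005	Caucasian	rs6265	243	73	6	206	103	13	322	322	FALSE	.	.	.	.	.	9
muschler_2011	Muschler	2011	Caucasian	rs6265	151	83	5	68	28	3	239	99	FALSE	.	44.1	38.4	.	.	7
nedic_2013	Nedic	2013	Caucasian	rs6265	458	197	20	609	274	31	675	915	FALSE	.	50.5	58.5	3.12	FALSE	8
pivac_2022	Pivac	2022	Caucasian	rs6265	440	190	20	600	263	55	650	918	FALSE	.	49	51	2.64	FALSE	8
sery_2011	Sery	2011	Caucasian	rs6265	109	55	3	195	89	5	167	289	FALSE	.	45.4	43.3	.	TRUE	7
wojnar_2009	Wojnar	2009	Caucasian	rs6265	39	17	3	27	25	8	59	60	FALSE	.	44.2	.	3.2	FALSE	9
zai_2018_rs6265	Zai	2018	Caucasian	rs6265	22	5	1	69	48	10	25	124	TRUE	.	37.9	.	1.95	FALSE	7
zai_2018_rs11030104	Zai	2018	Caucasian	rs11030104	21	7	1	65	51	11	26	124	TRUE	.	37.9	.	1.95	FALSE	7
zhang_2006	Zhang	2006	Caucasian	rs6265	220	100	7	166	74	10	327	250	FALSE	.	39.8	37.5	1.51	FALSE	9
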