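# Cohort variant table: 11 unique voltage-gated sodium channel variants
# in 10 sudden-unexpected-death-in-pediatrics cases (12 rows; one case
# carries two variants in cis, two siblings share one nonsense variant).
# parazscore_published / acmg_published are the original expert
# annotations, carried as descriptive inputs only.
gene	case_id	transcript	cdna	protein	af	sift	polyphen2_hvar	splice_likelihood	parazscore_published	acmg_published	inheritance	zygosity	age	hippocampus	notes	cohort	ref_aa	position	alt_aa	kind
SCN1A	Case1	NM_001165963.1	3886T>A	L1296M	8.17e-6	0.001	0.979	.	0.49	P	unknown	het	7 weeks	abnormal	in cis with E1308D; abnormal dentate gyrus	case	L	1296	M	missense
SCN1A	Case1	NM_001165963.1	3924A>T	E1308D	6.416e-4	0.281	0.727	.	-1.23	LP	unknown	het	7 weeks	abnormal	in cis with L1296M	case	E	1308	D	missense
SCN1A	Case2	NM_001165963.1	2045G>T	G682V	4.07e-6	0.003	0.478	.	-1.48	LP	unknown	het	2 months	abnormal	abnormal dentate gyrus	case	G	682	V	missense
SCN1A	Case3	NM_001165963.1	182T>C	L61P	0	0	0.783	.	1.23	LP	unknown	het	20 months	abnormal	end-folium sclerosis; atypical febrile seizures	case	L	61	P	missense
SCN3A	Case4	NM_006922.3	5411C>T	A1804V	2.44e-5	0	0.998	.	-0.49	VUS	unknown	het	4 months	.	.	case	A	1804	V	missense
SCN4A	Case5	NM_000334.3	2171A>G	K724R	0	0.001	0.953	.	0.25	P	inherited	het	5 months	normal	megalencephaly; normal hippocampus	case	K	724	R	missense
SCN4A	Case6	NM_000334.3	307T>G	F103V	2.03e-5	0.001	0.73	.	-0.25	VUS	inherited	het	3 months	abnormal	megalencephaly; abnormal dentate gyrus	case	F	103	V	missense
SCN9A	Case7	NM_002977.3	5624G>A	R1875Q	1.62e-5	0	0.734	.	0	VUS	inherited	het	8 years	abnormal	Chiari malformation 1; abnormal dentate gyrus	case	R	1875	Q	missense
SCN10A	Case4	NM_006514.2	4386+1G>C	.	1.22e-5	.	.	100	.	VUS	unknown	het	4 months	.	splice-site variant, same case as SCN3A A1804V	case	.	.	.	splice
SCN10A	Case8	NM_006514.2	305C>G	S102C	4.07e-6	0.002	0.701	.	-0.25	VUS	inherited	het	3 months 22 days	abnormal	megalencephaly; abnormal dentate gyrus	case	S	102	C	missense
SCN1B	Case9	NM_199037.4	536G>A	W179*	8.19e-6	.	.	.	.	LP	unknown	het	4 months	abnormal	sibling of Case10	case	W	179	*	nonsense
SCN1B	Case10	NM_199037.4	536G>A	W179*	8.19e-6	.	.	.	.	LP	unknown	het	2 months	.	sibling of Case9	case	W	179	*	nonsense
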