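# synthetic representative 76-gene clinical panel (approximate hg19 coordinates)
X	66760000	66950000	AR	HORMONE_RECEPTOR	0
6	152010000	152450000	ESR1	HORMONE_RECEPTOR	0
14	64690000	64800000	ESR2	HORMONE_RECEPTOR	0
11	100900000	101000000	PGR	HORMONE_RECEPTOR	0
20	46130000	46280000	NCOA3	HORMONE_RECEPTOR	0
5	142660000	142780000	NR3C1	HORMONE_RECEPTOR	0
15	51500000	51630000	CYP19A1	HORMONE_RECEPTOR	0
3	178860000	178960000	PIK3CA	PI3K_AKT_MTOR	0
5	67500000	67600000	PIK3R1	PI3K_AKT_MTOR	0
19	18260000	18300000	PIK3R2	PI3K_AKT_MTOR	0
14	105230000	105260000	AKT1	PI3K_AKT_MTOR	0
19	40730000	40790000	AKT2	PI3K_AKT_MTOR	0
1	243650000	244000000	AKT3	PI3K_AKT_MTOR	0
1	11160000	11330000	MTOR	PI3K_AKT_MTOR	0
10	89620000	89730000	PTEN	PI3K_AKT_MTOR	1
9	135760000	135820000	TSC1	PI3K_AKT_MTOR	0
16	2090000	2140000	TSC2	PI3K_AKT_MTOR	0
19	1200000	1230000	STK11	PI3K_AKT_MTOR	0
5	38930000	39080000	RICTOR	PI3K_AKT_MTOR	0
17	78510000	78940000	RPTOR	PI3K_AKT_MTOR	0
12	25360000	25400000	KRAS	MAPK	0
1	115250000	115260000	NRAS	MAPK	0
11	520000	540000	HRAS	MAPK	0
7	140430000	140620000	BRAF	MAPK	1
3	12620000	12710000	RAF1	MAPK	0
15	66680000	66780000	MAP2K1	MAPK	0
19	4090000	4120000	MAP2K2	MAPK	0
22	22110000	22220000	MAPK1	MAPK	0
7	55090000	55280000	EGFR	MAPK	1
17	37840000	37890000	ERBB2	MAPK	1
12	56470000	56500000	ERBB3	MAPK	0
2	212240000	213400000	ERBB4	MAPK	0
8	38270000	38330000	FGFR1	MAPK	0
10	123240000	123360000	FGFR2	MAPK	0
4	1790000	1810000	FGFR3	MAPK	0
4	55520000	55610000	KIT	MAPK	1
4	55090000	55160000	PDGFRA	MAPK	1
5	149490000	149540000	PDGFRB	MAPK	1
7	116310000	116440000	MET	MAPK	1
2	29420000	30140000	ALK	MAPK	1
10	43570000	43620000	RET	MAPK	0
6	117610000	117740000	ROS1	MAPK	0
17	29420000	29710000	NF1	MAPK	0
2	39210000	39350000	SOS1	MAPK	0
13	28570000	28670000	FLT3	MAPK	0
17	7570000	7590000	TP53	OTHER	0
13	48870000	49060000	RB1	OTHER	0
9	21970000	21990000	CDKN2A	OTHER	0
12	58140000	58150000	CDK4	OTHER	0
7	92230000	92460000	CDK6	OTHER	0
11	69450000	69470000	CCND1	OTHER	0
19	30300000	30320000	CCNE1	OTHER	0
8	128740000	128750000	MYC	OTHER	0
2	16080000	16090000	MYCN	OTHER	0
12	69200000	69240000	MDM2	OTHER	0
1	204480000	204530000	MDM4	OTHER	0
5	112040000	112180000	APC	OTHER	0
18	48550000	48610000	SMAD4	OTHER	0
7	128820000	128850000	SMO	OTHER	0
9	98200000	98280000	PTCH1	OTHER	0
20	57410000	57490000	GNAS	OTHER	0
9	80330000	80650000	GNAQ	OTHER	0
19	3090000	3120000	GNA11	OTHER	0
2	209100000	209120000	IDH1	OTHER	0
15	90620000	90650000	IDH2	OTHER	0
3	10180000	10190000	VHL	OTHER	0
9	4980000	5130000	JAK2	OTHER	0
19	17930000	17960000	JAK3	OTHER	0
9	133590000	133760000	ABL1	OTHER	0
20	35970000	36030000	SRC	OTHER	0
9	139380000	139440000	NOTCH1	OTHER	0
3	41240000	41280000	CTNNB1	OTHER	0
4	153240000	153460000	FBXW7	OTHER	0
11	108090000	108240000	ATM	OTHER	0
17	41190000	41280000	BRCA1	OTHER	0
13	32890000	32970000	BRCA2	OTHER	0
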