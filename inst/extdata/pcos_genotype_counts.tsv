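# Genotype counts from a PCOS case-control cohort (55 cases, 110 controls)
# genotyped across seven reproductive-axis SNPs with the three-primer
# HRM / AS-qPCR assays. Reference rows mark the wild-type genotype.
rsid	gene	genotype	cases	controls	reference
rs9939609	FTO	TT	20	72	TRUE
rs9939609	FTO	AT	13	23	FALSE
rs9939609	FTO	AA	22	15	FALSE
rs6185	GNRH1	GG	50	96	TRUE
rs6185	GNRH1	GC	5	14	FALSE
rs6185	GNRH1	CC	0	0	FALSE
rs6169	FSHB	CC	37	66	TRUE
rs6169	FSHB	CT	2	3	FALSE
rs6169	FSHB	TT	16	41	FALSE
rs6165	FSHR	GG	13	29	TRUE
rs6165	FSHR	GA	26	53	FALSE
rs6165	FSHR	AA	16	28	FALSE
rs1800447	LHB	TT	0	0	TRUE
rs1800447	LHB	CT	0	0	FALSE
rs1800447	LHB	CC	55	110	FALSE
rs34349826	LHB	AA	0	0	TRUE
rs34349826	LHB	AG	0	0	FALSE
rs34349826	LHB	GG	55	110	FALSE
rs2293275	LHCGR	AA	11	29	TRUE
rs2293275	LHCGR	GA	31	44	FALSE
rs2293275	LHCGR	GG	13	37	FALSE
rs1799817	INSR	CC	48	95	TRUE
rs1799817	INSR	CT	1	1	FALSE
rs1799817	INSR	TT	6	14	FALSE
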