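rsid	chrom	gene	effect_allele	other_allele	eaf	beta	se	pvalue	n
rs12498742	4	SLC2A9	A	G	0.77	0.373	0.006	1e-300	110347
rs2231142	4	ABCG2	T	G	0.11	0.217	0.009	1.0e-134	110347
rs1260326	2	GCKR	T	C	0.41	0.074	0.005	1.2e-44	110347
rs3741414	12	INHBC	T	C	0.24	-0.072	0.007	2.2e-25	110347
rs675209	6	RREB1	T	C	0.27	0.061	0.006	1.3e-23	110347
rs11264341	1	TRIM46	T	C	0.43	-0.050	0.006	6.2e-19	110347
rs653178	12	ATXN2	T	C	0.51	-0.035	0.005	7.2e-12	110347
rs1178977	7	BAZ1B	A	G	0.81	0.047	0.007	1.2e-12	110347
rs10480300	7	PRKAG2	T	C	0.28	0.035	0.006	4.1e-09	110347
rs1165151	6	SLC17A1	T	G	0.47	-0.091	0.005	7.0e-70	110347
rs2078267	11	SLC22A11	T	C	0.51	-0.073	0.006	9.4e-38	110347
rs7224610	17	HLF	A	C	0.58	-0.042	0.005	5.4e-17	110347
rs6598541	15	IGF1R	A	G	0.36	0.043	0.006	4.8e-15	110347
rs1394125	15	UBE2Q2	A	G	0.34	0.043	0.006	2.5e-13	110347
rs7193778	16	NFAT5	T	C	0.86	-0.046	0.008	8.2e-10	110347
rs17050272	2	INHBB	A	G	0.43	0.035	0.006	1.6e-10	110347
rs7188445	16	MAF	A	G	0.33	-0.032	0.005	1.6e-09	110347
rs17786744	8	STC1	A	G	0.58	-0.029	0.005	1.4e-08	110347
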