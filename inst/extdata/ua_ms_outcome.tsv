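rsid	chrom	effect_allele	other_allele	or	ci_low	ci_high	pvalue	n	source	proxy_rsid
rs12498742	4	A	G	1.00	0.96	1.04	0.961	38589	IMSGC	rs7442295
rs2231142	4	T	G	0.99	0.94	1.05	0.795	38589	IMSGC	NA
rs1260326	2	T	C	1.00	0.96	1.03	0.749	38589	IMSGC	NA
rs3741414	12	T	C	1.01	0.97	1.05	0.678	38589	IMSGC	NA
rs675209	6	T	C	1.04	1.00	1.08	0.048	38589	IMSGC	NA
rs11264341	1	T	C	1.03	0.99	1.06	0.109	38589	IMSGC	NA
rs653178	12	T	C	0.95	0.92	0.98	0.002	38589	IMSGC	NA
rs1178977	7	A	G	0.97	0.93	1.01	0.171	38589	IMSGC	rs17145713
rs10480300	7	T	C	1.02	0.99	1.06	0.267	38589	IMSGC	rs10224002
rs1165151	6	T	G	0.94	0.91	0.97	3.8e-4	27148	WTCCC2	rs9393672
rs2078267	11	T	C	0.97	0.94	1.00	0.082	27148	WTCCC2	NA
rs7224610	17	A	C	1.02	0.99	1.06	0.241	27148	WTCCC2	NA
rs6598541	15	A	G	0.99	0.95	1.03	0.606	27148	WTCCC2	rs3743264
rs1394125	15	A	G	0.97	0.93	1.01	0.106	27148	WTCCC2	NA
rs7193778	16	T	C	1.02	0.97	1.07	0.488	27148	WTCCC2	rs33063
rs17050272	2	A	G	1.01	0.97	1.04	0.718	27148	WTCCC2	rs6706968
rs7188445	16	A	G	0.97	0.93	1.01	0.160	27148	WTCCC2	rs17767383
rs17786744	8	A	G	1.00	0.96	1.04	0.900	27148	WTCCC2	rs1705699
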