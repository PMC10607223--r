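rsid	gene	ref_allele	alt_alleles
rs1045642	ABCB1	T	C
rs2032582	ABCB1	T	G,A
rs1128503	ABCB1	T	C
rs2273697	ABCC2	G	A
rs2231142	ABCG2	C	A
rs12208357	SLC22A1	C	T
rs34059508	SLC22A1	G	A
rs72552763	SLC22A1	GAT	delGAT
rs4149056	SLCO1B1	T	C
rs2306283	SLCO1B1	A	G
rs887829	UGT1A1	C	T
rs35742686	CYP2D6	A	delA
rs3892097	CYP2D6	G	A
rs1065852	CYP2D6	C	T
rs5030655	CYP2D6	T	delT
rs5030867	CYP2D6	A	C
rs5030865	CYP2D6	G	T,A
rs5030656	CYP2D6	TCT	delTCT
rs28371706	CYP2D6	C	T
rs28371725	CYP2D6	G	A
rs28399433	CYP2A6	T	G
rs2279343	CYP2B6	A	G
rs3211371	CYP2B6	C	T
rs3745274	CYP2B6	G	T
rs11572103	CYP2C8	A	T
rs10509681	CYP2C8	A	G
rs1058930	CYP2C8	C	G
rs1799853	CYP2C9	C	T
rs1057910	CYP2C9	A	C
rs4244285	CYP2C19	G	A
rs4986893	CYP2C19	G	A
rs28399504	CYP2C19	A	G
rs12248560	CYP2C19	C	T
rs55785340	CYP3A4	T	C
rs46464389	CYP3A4	delA	A
rs67666821	CYP3A4	delA	A
rs35599367	CYP3A4	C	T
rs776746	CYP3A5	A	G
rs10264272	CYP3A5	G	A
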