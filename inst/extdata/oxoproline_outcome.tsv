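SNP	gene	chrom	A1	A2	freq	b	se	p	N
rs11986602	EXOSC4	8	A	T	NA	-0.0196	0.0044	9.53e-06	NA
rs9987070	NA	7	C	G	NA	-0.0083	0.0071	0.2381	NA
rs10890517	NA	2	T	C	NA	-0.0139	0.0069	0.0427	NA
rs5764925	NA	22	A	G	NA	-0.0021	0.0050	0.6782	NA
rs13159409	NA	5	T	G	NA	-0.0075	0.0053	0.1535	NA
rs12294182	MICAL2	11	T	C	NA	0.0019	0.0041	0.6478	NA
rs2068157	AACSP1	5	T	C	NA	-0.0037	0.0048	0.4362	NA
rs9964014	DLGAP1	18	T	C	NA	-0.0060	0.0078	0.4388	NA
rs11605366	NA	11	T	C	NA	-0.0111	0.0043	0.0094	NA
rs12143589	NA	1	A	G	NA	-0.0024	0.0036	0.5034	NA
rs13013224	LOC105369165	2	C	G	NA	-0.0031	0.0035	0.3781	NA
rs306676	NA	13	A	G	NA	-0.0027	0.0041	0.5047	NA
rs9650466	MROH1	8	T	C	NA	0.0046	0.0028	0.0938	NA
rs1001210	ATXN1	6	T	C	NA	-0.0051	0.0037	0.1678	NA
rs17017431	TRAF5	1	A	T	NA	0.0022	0.0038	0.5628	NA
rs10853533	SLC14A2	18	A	C	NA	-0.0068	0.0043	0.1133	NA
rs2115151	SPATA5	4	A	T	NA	0.0024	0.0041	0.5561	NA
rs7015048	NA	8	T	C	NA	-0.0015	0.0028	0.5864	NA
rs9460424	NA	6	T	G	NA	-0.0053	0.0035	0.1328	NA
rs4646693	LRRK1	15	T	C	NA	-0.0001	0.0054	0.9909	NA
rs8092658	SLC14A2	18	A	C	NA	0.0001	0.0028	0.9828	NA
rs1578743	NA	10	A	C	NA	0.0026	0.0029	0.3664	NA
rs7973508	NA	12	A	G	NA	0.0007	0.0030	0.8245	NA
rs12464424	NA	2	T	C	NA	0.0055	0.0030	0.0651	NA
rs12611788	GALNT14	2	T	C	NA	-0.0062	0.0029	0.0301	NA
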