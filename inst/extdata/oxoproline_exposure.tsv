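SNP	gene	chrom	A1	A2	freq	b	se	p	N
rs11986602	EXOSC4	8	A	T	NA	-0.0620	0.0029	1.07e-104	NA
rs9987070	NA	7	C	G	NA	-0.0280	0.0059	2.43e-06	NA
rs10890517	NA	2	T	C	NA	-0.0197	0.0043	3.45e-06	NA
rs5764925	NA	22	A	G	NA	-0.0160	0.0031	1.91e-07	NA
rs13159409	NA	5	T	G	NA	-0.0148	0.0032	2.74e-06	NA
rs12294182	MICAL2	11	T	C	NA	0.0140	0.0029	1.07e-06	NA
rs2068157	AACSP1	5	T	C	NA	0.0137	0.0031	8.99e-06	NA
rs9964014	DLGAP1	18	T	C	NA	-0.0132	0.0025	1.80e-07	NA
rs11605366	NA	11	T	C	NA	-0.0122	0.0027	7.55e-06	NA
rs12143589	NA	1	A	G	NA	0.0118	0.0023	3.38e-07	NA
rs13013224	LOC105369165	2	C	G	NA	0.0113	0.0023	7.04e-07	NA
rs306676	NA	13	A	G	NA	0.0112	0.0024	2.48e-06	NA
rs9650466	MROH1	8	T	C	NA	0.0110	0.0020	3.80e-08	NA
rs1001210	ATXN1	6	T	C	NA	-0.0106	0.0023	3.80e-06	NA
rs17017431	TRAF5	1	A	T	NA	0.0105	0.0023	3.80e-06	NA
rs10853533	SLC14A2	18	A	C	NA	0.0103	0.0023	6.09e-06	NA
rs2115151	SPATA5	4	A	T	NA	0.0103	0.0022	3.75e-06	NA
rs7015048	NA	8	T	C	NA	0.0100	0.0015	3.16e-11	NA
rs9460424	NA	6	T	G	NA	-0.0097	0.0022	9.16e-06	NA
rs4646693	LRRK1	15	T	C	NA	-0.0090	0.0020	6.80e-06	NA
rs8092658	SLC14A2	18	A	C	NA	-0.0090	0.0020	6.80e-06	NA
rs1578743	NA	10	A	C	NA	0.0075	0.0016	1.70e-06	NA
rs7973508	NA	12	A	G	NA	-0.0073	0.0016	5.40e-06	NA
rs12464424	NA	2	T	C	NA	-0.0071	0.0016	7.47e-06	NA
rs12611788	GALNT14	2	T	C	NA	-0.0070	0.0015	5.51e-06	NA
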