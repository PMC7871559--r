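SNP	A1	A2	freq	b	se	p	N	chrom
snp0001	C	T	0.1682005324	0.07054259129	0.008454287214	7.181764109e-17	      50000	NA
snp0002	C	A	0.2870390088	0.06602257595	0.006990313525	3.558586652e-21	      50000	NA
snp0003	T	C	0.2854317542	-0.1082575701	0.007002078901	6.38254481e-54	      50000	NA
snp0004	C	A	0.1747571926	0.1104500247	0.008327058131	3.744261816e-40	      50000	NA
snp0005	G	T	0.2682761685	-0.1344491012	0.007137323021	3.723504047e-79	      50000	NA
snp0006	T	G	0.2047841564	-0.132705642	0.007836268555	2.492032245e-64	      50000	NA
snp0007	C	T	0.3719791488	-0.07740571571	0.006542649729	2.700904316e-32	      50000	NA
snp0008	C	T	0.4951371131	-0.1103923532	0.006324854464	3.224244103e-68	      50000	NA
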