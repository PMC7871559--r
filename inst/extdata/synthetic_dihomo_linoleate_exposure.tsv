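SNP	A1	A2	freq	b	se	p	N	chrom
snp0001	A	G	0.151545028	-0.07905284854	0.008818906829	3.13054964e-19	      50000	NA
snp0002	A	G	0.3680604935	-0.1190491291	0.006556961665	1.148146327e-73	      50000	NA
snp0003	T	C	0.2319159444	0.07467123506	0.007492561583	2.145965862e-23	      50000	NA
snp0004	T	G	0.1814908766	-0.07887925842	0.008204664721	6.981620347e-22	      50000	NA
snp0005	T	C	0.2473138259	0.1264525631	0.0073294069	1.066629544e-66	      50000	NA
snp0006	T	G	0.4129214235	-0.1177938723	0.00642270797	3.952001235e-75	      50000	NA
snp0007	T	G	0.1793935569	0.1273864754	0.008241933731	6.884690945e-54	      50000	NA
snp0008	G	A	0.1876311927	0.08522857578	0.008099735941	6.812368396e-26	      50000	NA
snp0009	T	G	0.2767799456	-0.1015157193	0.00706801496	8.871362967e-47	      50000	NA
snp0010	T	C	0.3569107471	0.1154477588	0.006600617422	1.694188479e-68	      50000	NA
snp0011	C	A	0.1305118853	-0.1466838653	0.009387352872	4.8662566e-55	      50000	NA
snp0012	A	C	0.190820965	0.1425167735	0.008047567815	3.554807351e-70	      50000	NA
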