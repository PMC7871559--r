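SNP	A1	A2	freq	b	se	p	N	chrom
snp0001	A	G	0.151545028	0.01895953375	0.003795988306	5.895054912e-07	     269867	NA
snp0002	A	G	0.3680604935	0.02065693888	0.00282236226	2.497797677e-13	     269867	NA
snp0003	T	C	0.2319159444	-0.01263200314	0.00322507956	8.973080239e-05	     269867	NA
snp0004	T	G	0.1814908766	0.007070980969	0.003531595462	0.0452626006	     269867	NA
snp0005	T	C	0.2473138259	-0.0179085591	0.003154851664	1.37467447e-08	     269867	NA
snp0006	T	G	0.4129214235	0.01853644909	0.002764574433	2.014175875e-11	     269867	NA
snp0007	T	G	0.1793935569	-0.02046622154	0.003547637442	7.975649051e-09	     269867	NA
snp0008	G	A	0.1876311927	-0.009858986767	0.003486430179	0.004686657903	     269867	NA
snp0009	T	G	0.2767799456	0.009460047412	0.003042338768	0.001874261771	     269867	NA
snp0010	T	C	0.3569107471	-0.01787729622	0.002841153335	3.12862133e-10	     269867	NA
snp0011	C	A	0.1305118853	0.02708554283	0.004040668807	2.03858584e-11	     269867	NA
snp0012	A	C	0.190820965	-0.01479049899	0.003463975061	1.956437005e-05	     269867	NA
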