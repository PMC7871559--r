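SNP	A1	A2	freq	b	se	p	N	chrom
snp0001	C	T	0.1682005324	0.0008700606648	0.003639042347	0.8110353632	     269867	NA
snp0002	C	A	0.2870390088	0.003451186351	0.003008893156	0.2513835574	     269867	NA
snp0003	T	C	0.2854317542	-0.002061600002	0.003013957415	0.4939640344	     269867	NA
snp0004	C	A	0.1747571926	0.001048673852	0.003584278177	0.7698462436	     269867	NA
snp0005	G	T	0.2682761685	-0.002515005085	0.003072171558	0.4129913625	     269867	NA
snp0006	T	G	0.2047841564	-0.004355883541	0.003373023934	0.1965690762	     269867	NA
snp0007	C	T	0.3719791488	0.001899048705	0.002816201865	0.500101693	     269867	NA
snp0008	C	T	0.4951371131	-0.00624240869	0.002722454614	0.02185180622	     269867	NA
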