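snp	effect_allele	other_allele	eaf	beta	se	pval
rs11967485	a	g	0.1093	-0.0063	0.0169	0.7097
rs1801725	t	g	0.1379	0.018	0.0151	0.2341
rs2281558	t	g	0.2614	0.0068	0.0113	0.5473
rs12150338	t	c	0.0979	0.0037	0.0186	0.8415
rs4074995	a	g	0.2943	0.0009	0.011	0.9363
rs9447004	a	g	0.4968	-0.0047	0.0109	0.6674
rs17711722	t	c	0.3936	0.0048	0.0129	0.710
rs1570669	a	g	0.6604	0.0191	0.0105	0.06948
rs7481584	a	g	0.2974	-0.0105	0.0112	0.3489
rs7336933	a	g	0.148	-0.0014	0.0135	0.9146
rs10491003	t	c	0.0913	-0.0327	0.0178	0.06655
rs2885836	a	g	0.2278	0.0058	0.0122	0.6333
rs780094	t	c	0.3917	0.0059	0.0111	0.5976
rs1550532	c	g	0.3201	0.0022	0.0106	0.8345
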