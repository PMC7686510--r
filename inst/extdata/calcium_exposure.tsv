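snp	gene	effect_allele	other_allele	eaf	beta	se	pval	r2_pct
rs10491003	GATA3	T	C	0.09	0.027	0.005	4.80E-09	0.05
rs11967485	ARID1B	g	a	0.9	0.026	0.005	9.40E-07	0.05
rs12150338	WDR81/SERPINF2	t	c	0.09	0.03	0.006	1.50E-06	0.06
rs1550532	DGKD	C	G	0.31	0.018	0.003	8.20E-11	0.06
rs1570669	CYP24A1	G	A	0.34	0.018	0.003	9.10E-12	0.06
rs17711722	VKORC1L1	T	C	0.47	0.015	0.003	8.20E-09	0.04
rs1801725	CASR	T	G	0.15	0.071	0.004	8.90E-86	0.51
rs2281558	PYGB	t	g	0.25	0.015	0.003	5.10E-06	0.03
rs2885836	RARBTOP2B	a	g	0.24	0.012	0.003	5.40E-05	0.02
rs4074995	RGS14/SLC34A1	a	g	0.28	0.013	0.003	4.60E-06	0.03
rs7336933	DGKH/KIAA0564	G	A	0.85	0.022	0.004	9.10E-10	0.05
rs7481584	CARS	G	A	0.7	0.018	0.003	1.20E-10	0.05
rs780094	GCKR	T	C	0.42	0.017	0.003	1.30E-10	0.06
rs9447004	CD109	a	g	0.48	0.012	0.003	3.30E-06	0.03
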