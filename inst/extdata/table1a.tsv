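chromosome	cytoband	start	end	size_mb	bac_n	direction	freq_pct	gene_n
3	p13-14.1	64934270	73536726	8.60	74	gain	73	23
6	p22.1	26562439	28452189	1.89	60	gain	70	31
9	q21.13	73445866	76242707	2.80	29	gain	70	8
10	q21.3	69354590	71006065	1.65	15	gain	55	23
10	q24.1	95664566	99431796	3.77	37	gain	58	44
12	p13.31-13.32	2363194	8268165	5.90	44	gain	60	58
13	q14.1-14.2	42340030	47097431	4.76	38	gain	80	22
17	p13.3	373082	2754327	2.38	20	gain	60	37
2	p23.2-23.3	25035233	33995335	8.96	75	loss	63	83
2	p24.1	21212355	23783250	2.57	18	loss	58	1
2	q35	215083214	215870969	0.79	9	loss	58	5
3	p21.3-22.3	33902686	44181635	10.28	82	loss	65	90
4	p15.2-15.31	22255381	24549727	2.29	24	loss	60	5
6	p22.2	23982002	25939112	1.96	68	loss	80	16
12	q15	67646357	69188647	1.54	11	loss	55	11
13	q13.3	35856763	39003721	3.15	27	loss	65	18
X	p22.31	5701499	5872842	0.17	2	loss	50	1
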