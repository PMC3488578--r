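chromosome	cytoband	start	end	size_mb	bac_n	direction	freq_pct	gene_n
2	p24.1-24.3	12723105	21045423	8.32	58	gain	55	21
2	q25.1	11704089	12544967	0.84	7	gain	50	2
3	p12.3-13	67690502	79574641	11.88	96	gain	70	22
3	p14.1-14.3	56804094	67550231	10.75	65	gain	50	26
3	p21.31-22.1	42559388	46459596	3.90	33	gain	60	57
3	p25.3-26.3	1711179	9591700	7.88	72	gain	55	20
6	p22.1-22.3	20951128	28567815	7.62	132	gain	60	97
9	q21.13	75834015	76513536	0.68	6	gain	70	5
13	q14.1-14.2	40944092	47097431	6.15	47	gain	80	24
17	p13.2-13.3	481074	4001084	3.52	13	gain	70	35
X	p22.11-22.2	16180300	22691476	6.51	49	gain	60	26
2	p22.3	32854381	33890229	1.04	6	loss	50	3
2	p24.3-25.1	31026798	31813698	0.79	6	loss	50	3
3	p11.1-12.1	84572959	90247330	5.67	46	loss	70	9
3	p22.2-22.3	32980614	36795763	3.82	13	loss	75	14
3	p23	31259835	32891762	1.63	13	loss	60	10
6	p21.2-22.1	29049491	39602226	10.55	86	loss	70	27
10	p23.1-23.2	82106537	89500949	7.39	79	loss	60	36
12	p12.31	8090287	9190860	1.10	7	loss	50	18
13	q13.3	35856763	36315193	0.46	5	loss	80	4
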