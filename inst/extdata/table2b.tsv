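chromosome	cytoband	start	end	size_mb	bac_n	a_direction	a_freq_pct	b_direction	b_freq_pct	diff_pct
2	p23.3	23804032	26257119	2.45	17	gain	60	none	0	60
3	p11.2-12.1	85893658	87649703	1.76	14	loss	100	loss	40	60
3	p14.2-14.3	56804094	61897044	5.09	33	gain	20	gain	80	60
3	p22.2-24.1	29648645	38540543	8.89	25	loss	70	none	0	70
4	p15.2-15.3	21407638	23952439	2.54	27	none	0	loss	80	80
6	p12.3	47804985	47961964	0.16	2	none	0	gain	60	60
6	p22.1-22.2	25985490	26318093	0.33	5	none	0	gain	50	50
6	q21.1	73325343	73596310	0.27	2	loss	60	none	0	60
9	q22.2-22.3	76902029	78697046	1.80	17	loss	50	gain	20	70
10	q21.2	74105644	74697200	0.59	6	none	0	gain	60	60
12	p13.3	8010296	9309215	1.30	11	loss	90	loss	10	80
12	q24.2	63460935	64329625	0.87	14	loss	10	loss	60	50
17	p22.2	15476489	15931167	0.45	4	gain	60	none	0	60
X	q21.3	87836131	89896378	2.06	17	none	0	gain	60	60
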