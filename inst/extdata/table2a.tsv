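chromosome	cytoband	start	end	size_mb	bac_n	a_direction	a_freq_pct	b_direction	b_freq_pct	diff_pct
2	p24.1	20863719	22199349	1.30	10	loss	85	loss	30	55
3	p25.2-25.3	9867502	12488641	2.60	18	loss	25	gain	40	65
6	p22.1	28165236	28452189	0.30	6	gain	85	gain	25	60
10	q22.3	77428562	79105320	1.70	17	gain	15	loss	45	60
10	q24.1	98845671	99207113	0.36	4	gain	50	gain	70	20
17	p13.1	7918593	7993947	0.10	2	loss	10	gain	45	55
17	q24.2	62769444	63340772	0.60	5	loss	60	none	0	60
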