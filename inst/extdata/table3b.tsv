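chromosome	cytoband	start	end	size_mb	bac_n	a_direction	a_freq_pct	b_direction	b_freq_pct	diff_pct
2	p22.2-22.3	35262506	36832851	1.57	11	none	0	gain	100	100
2	p25.1	8929622	11112217	2.18	16	gain	14	gain	100	86
3	p24.1-24.3	23113657	26730485	3.62	32	loss	7	loss	60	53
4	p15.2	25955365	26477816	0.52	4	none	0	gain	60	60
10	q24.2-24.3	100717385	104630288	3.91	44	none	0	loss	100	100
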