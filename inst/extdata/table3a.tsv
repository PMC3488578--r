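chromosome	cytoband	start	end	size_mb	bac_n	a_direction	a_freq_pct	b_direction	b_freq_pct	diff_pct
6	p21.2	39548717	39877219	0.32	13	none	0	loss	62	62
6	p22.3	21096443	22252887	1.15	39	none	0	gain	66	66
17	p13.3	2443685	3461082	1.01	9	gain	21	gain	71	50
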