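stratum	model	order	NH	NL	beta_H	beta_L	Wmax	OR_H	OR_L	p_perm	MFS	Score	priority
male	alcohol x rs5751909	2	1	2	0.147	-0.253	24.98	1.16	0.78	0	80.5	86.4	Highest
male	alcohol x smoking x rs5751909	3	1	2	0.151	-0.352	34.38	1.16	0.70	0	62.2	73.5	High
male	alcohol x rs5751909 x rs5760489	3	1	4	0.154	-0.295	31.86	1.17	0.74	0	59.9	68.7	High
male	alcohol x smoking x rs5751909 x rs5760489	4	1	4	0.148	-0.408	43.69	1.16	0.66	0	51.3	65.9	High
male	alcohol x rs11546155 x rs5751909	3	1	2	0.163	-0.284	28.12	1.18	0.75	0	61.0	64.6	High
male	alcohol x rs5751909 x rs11657054	3	1	4	0.202	-0.264	27.01	1.22	0.77	0	62.2	64.0	High
male	alcohol x rs5751909 x rs4820599	3	1	3	0.159	-0.324	27.54	1.17	0.72	0	59.3	62.7	High
male	alcohol x rs5751909 x rs2100986	3	1	4	0.249	-0.259	25.98	1.28	0.77	0	59.3	60.6	High
female	smoking x rs8140505	2	3	2	0.421	-0.389	68.96	1.52	0.68	0	54.4	68.1	High
female	smoking x rs5751909	2	2	3	0.421	-0.421	67.85	1.52	0.66	0	54.9	67.8	High
female	smoking x rs5760489	2	2	1	0.427	-0.209	68.69	1.53	0.81	0	53.0	67.0	High
female	smoking x rs2275984	2	3	1	0.421	-0.196	67.85	1.52	0.82	0	53.7	67.0	High
female	smoking x rs2267073	2	3	2	0.421	-0.221	67.85	1.52	0.80	0	52.3	66.1	High
female	smoking x rs4820599	2	2	1	0.427	-0.201	68.69	1.53	0.82	0	50.7	65.4	High
female	smoking x rs11546155	2	2	1	0.415	-0.256	64.50	1.51	0.77	0	50.7	63.3	High
female	smoking x rs5760489 x rs8140505	3	6	2	0.429	-0.237	76.68	1.54	0.79	0	46.3	62.4	High
female	smoking x rs11657054	2	2	1	0.411	-0.206	62.85	1.51	0.81	0	49.0	61.3	High
female	smoking x rs2100986	2	2	1	0.411	-0.221	62.85	1.51	0.80	0	48.9	61.2	High
female	smoking x rs5751909 x rs8140505	3	5	2	0.414	-0.230	71.62	1.51	0.79	0	47.5	61.0	High
female	smoking x rs5751909 x rs2275984	3	5	1	0.430	-0.298	70.41	1.54	0.74	0	47.1	60.1	High
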