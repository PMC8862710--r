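lg	size_cM	n_snps
1	279	37
2	152	30
3	224	56
4	137	36
5	168	49
6	192	24
7	146	24
8	172	22
9	182	29
10	171	15
11	186	22
12	64	16
13	140	8
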