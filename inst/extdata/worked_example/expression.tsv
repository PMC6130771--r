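gene_id	pm1	e1	e2	m1	l1	l2
g01	16	8	4	2	1	0
g02	8	4	2	1	0	0
g03	2	8	16	4	2	1
g04	1	4	8	2	1	0
g05	0	2	4	16	4	2
g06	1	2	8	16	8	2
g07	0	1	2	4	16	8
g08	0	0	1	2	8	16
g09	1	1	2	4	8	16
g10	4	4	4	4	4	4
g11	0.5	0.5	0.5	0.5	0.5	0.5
g_const	3	3	3	3	3	3
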