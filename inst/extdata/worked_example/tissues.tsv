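gene_id	brain	gut	muscle	ovary	testis
g01	5	4	5	6	5
g02	6	5	4	5	5
g03	8	2	1	1	0
g04	4	4	5	4	4
g05	6	6	5	5	4
g06	5	5	5	6	5
g07	0	0	0	0	5
g08	1	0	0	0	8
g09	2	4	8	1	1
g10	8	8	8	8	8
g11	0	0	0	0	6
g_const	2	4	8	2	3
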