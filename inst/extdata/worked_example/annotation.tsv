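gene_id	omega0	phylostratum	paralog_count	connectivity	is_retrogene
g01	0.1	2	1	10	FALSE
g02	0.12	3	2	8	FALSE
g03	0.08	1	0	20	FALSE
g04	0.1	2	1	15	FALSE
g05	0.04	1	0	30	FALSE
g06	0.05	1	1	25	FALSE
g07	0.2	5	4	5	TRUE
g08	0.25	6	6	3	TRUE
g09	0.18	4	3	6	TRUE
g10	0.15	3	2	12	FALSE
g11	0.3	6	5	2	TRUE
g_const	0.15	2	1	9	FALSE
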