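group	length_cm	n_markers	n_scaffolds	anchored_kb
1	118.211	28	10	4543
2	70.185	13	4	2742
3	38.397	8	6	661
4	108.488	18	7	3136
5	34.148	10	2	2395
6	17.118	6	5	391
7	2.681	5	1	391
8	19.473	5	3	3460
9	1.605	5	1	880
10	1.295	4	4	1048
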