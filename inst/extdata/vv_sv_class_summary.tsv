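type	count	length_bp
insertion	559	160549
deletion	371	448893
duplication	11	88643
inversion	1	47707
complex	1	1682
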