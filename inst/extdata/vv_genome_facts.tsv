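key	value
genome_size_bp	37200000
original_scaffolds	302
primer_pairs_designed	204
effective_markers	104
mapped_markers	102
isolates_total	235
homokaryons	192
total_genes	11534
genes_on_anchored_scaffolds	5172
sv_total_length_bp	747474
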