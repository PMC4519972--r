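Reference summary tables from the published V. volvacea SV-marker mapping
study (strain pair PYd21/PYd15, 192-homokaryon single-spore population):
per-SV-class counts and lengths, per-linkage-group map summaries, and
genome-level constants. Used by the examples and by scripts/acceptance.R to
recompute the study's derived statistics with this package's arithmetic.
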