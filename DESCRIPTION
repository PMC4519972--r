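Package: svmap
Title: Structural-Variation Markers and Linkage Map Construction for Haploid Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects structural-variation (SV) loci between two haploid fungal
    strains from discordant paired-end alignment signatures, derives co-dominant
    PCR markers whose two parental amplicons differ in length, genotypes a
    single-spore-isolate mapping population, builds a genetic linkage map
    (LOD-threshold grouping, greedy marker ordering with ripple refinement,
    Kosambi map distances), and anchors genome scaffolds to the map. Includes a
    full simulator -- parental genome pair with a known variant spectrum,
    liftover-exact discordant read pairs, and no-interference meiosis -- so
    every stage can be validated against recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
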