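Package: cleavemap
Title: Mapping and Quantification of Endoribonuclease Cleavage Sites from
    Dual RNA-Seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies endoribonuclease (toxin) cleavage of bacterial
    transcripts at single-nucleotide resolution from strand-specific
    paired-end fragment data. Combines a fragmented coverage library with an
    unfragmented 5'-end library to compute per-nucleotide cleavage ratios and
    5'-end ratios, calls cleavage sites with fixed evidence thresholds,
    derives cleavage specificity (sequence motif with per-column information
    content, subcodon preference, 5'-to-3' positional density), summarizes
    cleavage per gene and gene class, and tests cleavage-site overlap between
    two nucleases by label permutation against an exact hypergeometric null.
    Includes a ground-truthed generative simulator of motif-directed
    transcript cleavage and both library types' sampling processes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cleavemap-package.R'
    'genes.R'
    'io.R'
    'overlap.R'
    'peaks.R'
    'pipeline.R'
    'profiles.R'
    'simulate.R'
    'specificity.R'
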