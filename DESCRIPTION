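Package: panfam
Title: Pangenome Gene Family Characterization with Synthetic Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes gene families across pangenome assemblies:
    position-specific scoring matrix (PSSM) domain scanning with a
    calibrated exclusion threshold and overlap-rule family classification;
    assembly-level validation of presence/absence (PAV) and copy-number
    (CNV) variation by seed-and-extend genomic search; exon-aware
    frameshift detection with alternative translation-start rescue and
    annotation reconciliation; reference-based paralog copy labeling;
    neighbor-joining phylogenies of family proteins; and k-mer frequency
    PCA of genotype-level protein variation with cos2 contributions and
    leave-family-out driver ranking. A synthetic pangenome generator
    plants gene deletions, tandem and dispersed duplications, 1-bp coding
    indels, partial domain deletions and annotation truncations on a
    neutral genomic background, with a machine-readable truth table, so
    that every stage of the pipeline is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
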