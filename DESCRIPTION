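Package: svfusion
Title: Patient-Specific Fusion-Gene Genomic Breakpoint Detection from
    Targeted Capture Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects patient-specific genomic breakpoints of the
    ETV6-RUNX1 (t(12;21)(p13;q22)) fusion and related rearrangements from
    targeted-capture paired-end sequencing. Read pairs are classified
    against a robust insert-size model, inter-chromosomal and discordant
    pairs are clustered into candidate breakpoints, junction-spanning
    reads are assembled into contigs and resolved to base-pair precision
    with microhomology and untemplated-insertion accounting. Junctions are
    typed into the four strand-pair orientation classes (a-d), derivative
    chromosomes are reconstructed with centromere-viability accounting,
    two-way and three-way translocation events are interpreted, FISH
    signal patterns are predicted, and diagnosis/relapse clone pairs are
    compared. Includes a capture-sequencing read simulator with truth
    sets, cohort-level statistics (type census, Kaplan-Meier and log-rank
    survival, exact hypergeometric association), and export of fused
    breakpoint flanking sequences for minimal residual disease assay
    design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'genome.R'
    'utils.R'
    'align.R'
    'junctions.R'
    'cohort.R'
    'derivatives.R'
    'events.R'
    'io.R'
    'mrd.R'
    'simulate.R'
    'svcall.R'
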