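Package: spliceLesion
Title: Interpretation of Cryptic Splice-Altering Intronic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for interpreting intronic single-nucleotide variants that
    disrupt pre-mRNA splicing outside the essential GT/AG dinucleotides.
    Represents genes as exon/intron models with HGVS coding-coordinate
    mapping, reconstructs aberrant mature transcripts (complete and partial
    intron retention, exon skipping/truncation/extension, cryptic-exon
    insertion), locates premature termination codons and calls
    nonsense-mediated decay sensitivity by the exon-junction rule, scans
    proximal intronic sequence for AG-exclusion-zone breaks, branchpoint-window
    membership and SR-protein binding motifs, predicts RT-PCR amplicons and
    dual-tagged minigene constructs in silico, and summarizes variant
    recurrence and phenotype specificity over a bundled 46-variant cohort
    table of splice-altering MYBPC3 variants in hypertrophic cardiomyopathy.
    A seeded synthetic-data generator produces multi-exon gene models with
    planted spliceogenic lesions and simulated cohorts for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
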