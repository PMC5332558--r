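Package: polwave
Title: RNA Polymerase II Elongation Wave-Front Analysis from Nascent-RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcription-elongation kinetics and alternative
    last exon (ALE) isoform switching from nascent-RNA sequencing (GRO-seq) data.
    Builds normalized strand-specific coverage from aligned reads, extracts
    TSS-anchored gene windows and trimmed-mean meta-gene profiles, calls per-gene
    transcription wave-fronts after DRB release with an island/gap change-point
    caller, estimates elongation rates pairwise and by line fit, locates cohort
    wave-fronts mathematically from meta-profile differences (loess zero crossing
    with derivative-half refinement), quantifies alternative-isoform events with
    splicing-index effect sizes and a conjugate two-proportion Bayes factor, and
    computes small closed-form assay statistics (Livak delta-delta-CT, fraction
    enrichment, low/high transcription ratio). A synthetic-data generator with
    known kinetic and isoform-mixing ground truth makes every stage testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
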