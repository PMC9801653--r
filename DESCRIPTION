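Package: scvannotate
Title: Transcript Model Selection and Re-Annotation of Compact Fungal
    Genomes from Multi-Sample RNA-seq Assemblies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-annotates compact (gene-dense) genomes from collections of
    RNA-seq derived transcript assemblies.  Implements the Successive
    Coverage Values (SCV) selection scheme that retains, per gene, the
    transcript predictions clearing the most restrictive coverage threshold
    of a discrete ladder; annotates 5'/3' UTRs and alternative transcription
    start/end sites with per-sample provenance; classifies alternative
    splicing events (alternative 5'/3' splice sites and exon skipping from
    exon-exon junctions, intron retention from binned intron coverage under
    a four-threshold gate); discovers novel transcriptionally active regions
    and antisense transcripts from the unassigned prediction pool; and
    computes TSS-centered chromatin metaprofiles.  Ships a synthetic-data
    generator with planted ground truth so every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
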