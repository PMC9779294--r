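Package: mecp2scan
Title: Isoform Annotation and Epigenomic Segment Calling at the MECP2 Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-silico analysis of the human MECP2 locus and
    MECP2-like synthetic loci: global protein alignment of splice-variant
    isoforms against the reference MeCP2E1/MeCP2E2 isoforms with per-residue
    exon provenance, projection of functional domains (MBD, TRD, NLS, ...)
    through alignments with completeness classification, transcription
    start site relative coordinate transforms for minus-strand genes,
    consensus calling of enriched or accessible segments across multi-sample
    ChIP-seq/DNase-seq/ATAC-seq signal tracks, detection of consistently
    hypomethylated regions from bisulfite methylation fractions, and
    co-localization reporting among fragment sets and cis-regulatory
    elements. Includes a deterministic synthetic-data generator that plants
    known splice variants, enrichment segments and hypomethylated regions
    so every stage is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
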