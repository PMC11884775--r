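Package: nlromer
Title: Refining Plant NLRomes with Resistance Gene Enrichment Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles resistance gene enrichment sequencing (RenSeq) read
    coverage, motif-based NLR locus predictions, and an existing genome
    annotation to detect and repair missing, wrongly annotated, and fused
    NLR (nucleotide-binding leucine-rich repeat receptor) gene models.
    Provides per-base enrichment depth and a >=50x region caller with
    flanking extraction, a six-frame degenerate-motif NLR locus scanner,
    ORF-based de novo gene prediction inside problem regions with
    longest-isoform selection, domain-architecture classification
    (full/partial, TNL/CNL/RNL, TIR-only, C-JID, integrated domains),
    hybridization-capture bait tiling with N-run replacement, cohort
    summaries per chromosome, and a fully seeded synthetic-data generator
    (genome with planted NLRs, corrupted annotation, enriched paired reads
    with a truth SAM) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
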