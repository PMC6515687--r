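Package: targetome
Title: Deletion-Based CLIP Targetome and miRNA Transcript Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterizing an RNA-binding protein's
    targetome from HITS-CLIP, RNA-seq and small-RNA sequencing data:
    crosslink-site calling from reverse-transcription deletions in CLIP
    alignments, sequence and base-pairing context profiling around sites,
    metagene coverage profiles with 3'-UTR-length tercile stratification,
    classification of CLIP reads relative to miRNA hairpins (categories I-V)
    with mature/pre-/pri-miRNA form calls, windowed quantification of miRNA
    primary transcripts across conditions, crosslink-to-splice-site distance
    mapping, and percent-intron-retention statistics for mirtrons. Includes a
    fully deterministic synthetic-data generator with planted ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    GenomeInfoDb,
    Biostrings,
    XVector,
    rtracklayer,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
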