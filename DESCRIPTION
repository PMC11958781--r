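Package: succer
Title: Differential Histone-Mark Enrichment Analysis and Multi-Omics
    Integration for CUT&Tag Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline linking differential histone-modification
    enrichment measured by CUT&Tag to differential gene expression,
    transcription-factor regulation and pathway membership. Calls
    differentially enriched regions (DERs) from consensus peaks by a
    fold-change rule on group-mean RPKM, annotates them against gene models,
    assigns them to nearest genes within 100 kb of a TSS, correlates region
    and expression fold changes, scans position weight matrices around peak
    summits for motif enrichment and occurrence profiling, identifies
    differentially expressed transcription factors and their promoter-proximal
    targets, and performs hypergeometric gene-set over-representation.
    Includes a fully deterministic synthetic-data generator with planted
    ground truth (negative-binomial region signal, correlated expression,
    planted motifs and gene sets) so the whole pipeline can be validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    stats,
    tools,
    utils,
    IRanges,
    S4Vectors,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
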