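Package: adipomem
Title: Transcriptional and Epigenetic Obesogenic Memory Analysis for
    Adipose Tissue Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for detecting obesogenic memory in adipose
    tissue multi-omic data. Implements differential-expression calling on
    single-nucleus counts (Wilcoxon rank-sum with fold-change and adjusted-p
    cut-offs), a restored-versus-memory retention classifier across obesity
    and weight-loss contrasts, exact-conditional negative-binomial tests for
    histone-mark and accessibility region counts, rule-based enhancer
    definition from binned mark tracks, promoter and enhancer trajectory
    classification, region-to-gene linkage, peak fold enrichment, and a
    multi-modality scorer that attributes persistent or rebound
    transcriptional changes to epigenetic alterations. Ships a synthetic
    data generator with planted ground truth so the full pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
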