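Package: ExomePopGen
Title: Population-Genetic Analysis of Exome Variant Call Sets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream population-genetic analysis of exome capture variant
    call sets: heuristic site filtering and call-set intersection QC
    (Ts/Tv, fraction known), short-indel equivalence merging, codon
    degeneracy and amino-acid effect annotation, per-base heterozygosity
    under coverage/callability rules, allele frequency spectrum
    construction with hypergeometric projection, Watterson's theta and the
    neutral theta/x expectation, cross-population minor-allele sharing
    with exact down-sampling and bootstrap confidence intervals,
    allele-frequency-binned functional enrichment tests with error-rate
    correction, and validation-assay contingency arithmetic. Includes a
    multi-population synthetic cohort generator with known ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
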