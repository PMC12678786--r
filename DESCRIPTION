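Package: offonome
Title: On/Off Gene Expression States from Base-Resolution RNA-Seq Coverage Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the Level of Shape Similarity (LSS), a cosine similarity
    between each sample's log-adjusted base-resolution coverage vector for a
    gene and an iteratively refined cohort mean profile, and binarizes it into
    per-sample on/off expression states. Provides BAM/GTF/BED12 coverage
    extraction, a plain-text cohort store, RNA-degradation (3'-bias) sample
    filtering by pooled coverage-decay rates, offonome gene-set definition
    (genes off in at least a given fraction of a cohort), Venn partitioning of
    gene sets across cohorts, a count-based low-expression filter for
    comparison, Ward hierarchical clustering of binary state matrices with
    majority-label classification rates, and a negative-binomial coverage
    simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
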