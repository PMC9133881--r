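Package: placodeCeRNA
Title: Stage- and Tissue-Specific ceRNA Triple Nomination for Hair Placode Formation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of a multi-omic integration pipeline that
    nominates stage- and tissue-specific competing-endogenous-RNA (ceRNA)
    triples (lncRNA-miRNA-mRNA) for embryonic hair placode formation.
    Includes a negative-binomial Wald differential-expression stage with
    median-of-ratios normalization and Benjamini-Hochberg FDR, lncRNA
    candidate filtering with a pluggable coding-potential scorer, cis (100 kb
    window), trans (expression correlation) and miRNA seed-match target
    assignment, trend-model ceRNA triple assembly, a weighted co-expression
    core (soft-threshold selection by scale-free fit, topological overlap,
    module eigengenes, module-trait association, kME hub calling), and a
    synthetic-data generator with planted ground truth so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cerna.R'
    'coexpr.R'
    'diffexpr.R'
    'ncrna_filter.R'
    'pipeline.R'
    'placodeCeRNA-package.R'
    'synthio.R'
    'targets.R'
    'utils_bio.R'
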