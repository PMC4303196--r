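Package: regact
Type: Package
Title: Transcription Factor Regulatory Activity Scoring for Survival
    Prognosis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers per-sample regulatory activity of a transcription
    factor from the relative expression of its ChIP-seq-derived target
    genes, using a signed Kolmogorov-Smirnov-type rank statistic with a
    permutation null. Builds consensus target-gene signatures from
    TSS-proximal binding signal with Benjamini-Hochberg FDR control,
    tests activity time courses for cell-cycle periodicity with Fisher's
    g-test, relates activity groups to survival outcome via
    Kaplan-Meier, log-rank and Cox proportional-hazards models
    (including gene-wise survival screens, signature enrichment and
    Nottingham Prognostic Index risk groups), and assigns intrinsic
    molecular subtypes by Spearman correlation to published centroids.
    Ships simulators for activity-driven expression cohorts with
    survival outcomes, periodic time courses, centroid-structured
    subtypes and TSS-proximal binding signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    survival,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    BiocGenerics,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, Survival, ChIPSeq, GeneSetEnrichment,
    Classification, CellCycle
RoxygenNote: 7.3.3
Collate:
    'regact-package.R'
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'signature.R'
    'activity.R'
    'periodicity.R'
    'survival.R'
    'subtype.R'
    'simulate.R'
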