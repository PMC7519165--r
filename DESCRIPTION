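Package: ConvergentOmics
Title: Multi-Omic Subtyping of Brain Samples by Similarity Network Fusion
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of matched mRNA expression, miRNA
    expression, DNA methylation and histone acetylation (H3K27ac) profiles
    from case/control brain cohorts. Implements similarity network fusion
    over covariate-adjusted differential features with spectral
    bipartition into a convergent and a disparate molecular subtype, a
    cascade of availability-pattern logistic classifiers for samples
    missing one or more assays, per-feature linear mixed-model
    differential statistics with a subject-level random intercept,
    methylation probe collapsing onto promoters and gene bodies,
    H3K27ac peak-to-gene linkage through promoter overlap, eQTL and Hi-C
    evidence, consensus signed-bicor topological-overlap network modules,
    and the associated enrichment statistics. A synthetic cohort
    generator with ground-truth subtype structure and a toy genome makes
    every stage testable without access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    lme4,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Transcriptomics, Epigenetics, Clustering, Network,
    DifferentialExpression, GeneRegulation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ConvergentOmics-package.R'
    'differential.R'
    'snf.R'
    'cascade.R'
    'genomic-features.R'
    'linkage.R'
    'networks.R'
    'synthetic-cohort.R'
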