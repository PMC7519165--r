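#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame
NULL

#' Names of the four omics layers
#'
#' The four molecular layers integrated by the subtyping pipeline, in their
#' canonical order: mRNA expression, miRNA expression, DNA methylation
#' (promoter-collapsed beta values) and histone acetylation (H3K27ac peak
#' quantifications).
#'
#' @return Character vector of length four.
#' @export
#' @examples
#' omicLayerNames()
omicLayerNames <- function() c("mRNA", "miRNA", "meth", "acetyl")

#' CohortConfig: parameters of the synthetic multi-omic cohort
#'
#' Describes the study conditions emulated by [generateCohort()]: cohort
#' composition (ASD and control subjects, paired cortical regions), the
#' latent two-subtype structure among cases (a convergent subtype carrying a
#' shared differential signature across all four layers, and a disparate
#' subtype indistinguishable from controls), per-layer feature counts and
#' planted effect sizes, nuisance covariate effects, per-layer missingness,
#' and the random seed.
#'
#' @slot nSubjectsASD integer, number of ASD subjects.
#' @slot nSubjectsControl integer, number of control subjects.
#' @slot pPairedRegions probability that a subject contributes both a
#'   frontal and a temporal cortex sample (otherwise one region at random).
#' @slot fracConvergent fraction of ASD subjects in the convergent subtype;
#'   the convergent count is `round(frac * n)` (ties to even).
#' @slot fracDiscordant fraction of *paired* convergent subjects that are
#'   convergent in only one of their two regions (region-discordant).
#' @slot nFeatures named integer vector, features per layer.
#' @slot nDiffFeatures named integer vector, truly differential features per
#'   layer.
#' @slot effectSize named numeric vector, standardized mean shift (in SD
#'   units of the feature noise) carried by differential features in
#'   convergent samples.
#' @slot crossLayerCorr correlation with which the subject-level latent
#'   severity score propagates into each layer (1 = identical score in all
#'   four layers).
#' @slot severitySpread SD of the latent severity score around its mean of 1.
#' @slot subjectInterceptSd SD of the per-subject random intercept shared by
#'   both regional samples of a subject (makes the subject random effect of
#'   the differential models identifiable when regions are paired).
#' @slot covariateEffects named numeric vector, SD-unit scale of the additive
#'   nuisance covariate effects injected into all features.
#' @slot missingness named numeric vector, per-layer probability that a
#'   sample is unobserved in that layer.
#' @slot seed integer random seed.
#' @export
setClass("CohortConfig", representation(
    nSubjectsASD = "integer",
    nSubjectsControl = "integer",
    pPairedRegions = "numeric",
    fracConvergent = "numeric",
    fracDiscordant = "numeric",
    nFeatures = "integer",
    nDiffFeatures = "integer",
    effectSize = "numeric",
    crossLayerCorr = "numeric",
    severitySpread = "numeric",
    subjectInterceptSd = "numeric",
    covariateEffects = "numeric",
    missingness = "numeric",
    seed = "integer"
))

setValidity("CohortConfig", function(object) {
    msg <- NULL
    lay <- omicLayerNames()
    probs <- c(object@pPairedRegions, object@fracConvergent,
               object@fracDiscordant, object@missingness)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "probabilities and fractions must lie in [0,1]")
    for (s in c("nFeatures", "nDiffFeatures", "effectSize", "missingness")) {
        if (!identical(names(slot(object, s)), lay))
            msg <- c(msg, sprintf("'%s' must be named by %s", s,
                                  paste(lay, collapse = ", ")))
    }
    if (is.null(msg) && any(object@nDiffFeatures > object@nFeatures))
        msg <- c(msg, "nDiffFeatures must not exceed nFeatures")
    if (!all(is.finite(object@effectSize)))
        msg <- c(msg, "effect sizes must be finite")
    if (object@nSubjectsASD < 1L || object@nSubjectsControl < 1L)
        msg <- c(msg, "need at least one subject per diagnosis group")
    if (is.null(msg)) TRUE else msg
})

#' GenomeAnnotation: toy or real genome annotation for the linkage stages
#'
#' Holds the genomic entities consumed by probe collapsing and peak-to-gene
#' linkage: genes (stranded, with TSS/TES implied by strand), CpG probes
#' (1-bp ranges at the CpG position), H3K27ac peaks, eQTL pairs (eSNP
#' position + target gene) and Hi-C contacts (two anchors + interaction
#' FDR). Ranges are stored as `GRanges` (1-based closed, the Bioconductor
#' convention); BED input/output converts at the boundary.
#'
#' @slot genes `GRanges` with metadata column `gene_id` (unique) and `name`.
#' @slot probes `GRanges` of width 1 with metadata column `probe_id`.
#' @slot peaks `GRanges` with metadata column `peak_id`.
#' @slot eqtl `data.frame` with columns `snp_id`, `chrom`, `pos` (1-based
#'   position of the eSNP), `gene_id`.
#' @slot hic `data.frame` with columns `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB` (1-based closed anchors) and `fdr`.
#' @export
setClass("GenomeAnnotation", representation(
    genes = "GRanges",
    probes = "GRanges",
    peaks = "GRanges",
    eqtl = "data.frame",
    hic = "data.frame"
))

setValidity("GenomeAnnotation", function(object) {
    msg <- NULL
    gid <- object@genes$gene_id
    if (is.null(gid) || anyDuplicated(gid))
        msg <- c(msg, "genes must carry unique 'gene_id' metadata")
    if (length(object@probes) && is.null(object@probes$probe_id))
        msg <- c(msg, "probes must carry 'probe_id' metadata")
    if (length(object@peaks) && is.null(object@peaks$peak_id))
        msg <- c(msg, "peaks must carry 'peak_id' metadata")
    if (nrow(object@hic) &&
        (!"fdr" %in% names(object@hic) ||
         any(object@hic$fdr < 0 | object@hic$fdr > 1)))
        msg <- c(msg, "hic contacts need an 'fdr' column in [0,1]")
    if (is.null(msg)) TRUE else msg
})

setClassUnion("GenomeAnnotationOrNULL", c("GenomeAnnotation", "NULL"))

#' MultiOmicCohort: one cohort across the four omics layers
#'
#' The central data container: a list of feature-by-sample numeric matrices
#' (one per layer, possibly covering different subsets of the cohort's
#' samples), per-sample metadata, optional ground-truth labels (for
#' synthetic cohorts) and an optional genome annotation.
#'
#' @slot layers `SimpleList` of numeric matrices, rows = features,
#'   columns = samples; column names are sample IDs drawn from `sampleData`.
#' @slot sampleData `DataFrame`, one row per sample; must contain columns
#'   `sample_id`, `subject_id`, `diagnosis` (`ASD`/`Control`), `region`
#'   (`Frontal`/`Temporal`) plus covariates.
#' @slot truth list with elements `subject_subtype`, `sample_subtype`
#'   (named character vectors with values `convergent`/`disparate`/
#'   `control`) and `diff_features` (per-layer data.frame of feature, sign)
#'   for synthetic cohorts; empty list otherwise.
#' @slot annotation `GenomeAnnotation` or `NULL`.
#' @export
setClass("MultiOmicCohort", representation(
    layers = "SimpleList",
    sampleData = "DataFrame",
    truth = "list",
    annotation = "GenomeAnnotationOrNULL"
))

setValidity("MultiOmicCohort", function(object) {
    msg <- NULL
    sd <- object@sampleData
    need <- c("sample_id", "subject_id", "diagnosis", "region")
    if (!all(need %in% colnames(sd)))
        msg <- c(msg, paste("sampleData needs columns:",
                            paste(setdiff(need, colnames(sd)), collapse = ", ")))
    else {
        ids <- sd$sample_id
        if (anyDuplicated(ids)) msg <- c(msg, "duplicate sample_id")
        for (nm in names(object@layers)) {
            m <- object@layers[[nm]]
            if (!is.matrix(m) || !is.numeric(m))
                msg <- c(msg, sprintf("layer '%s' is not a numeric matrix", nm))
            else if (!all(colnames(m) %in% ids))
                msg <- c(msg, sprintf("layer '%s' has samples absent from sampleData", nm))
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' SNFParams: similarity network fusion parameters
#'
#' @slot K neighbourhood size of the local (K-nearest-neighbour) kernel.
#' @slot alpha kernel bandwidth scale \eqn{\mu} of the scaled exponential
#'   similarity kernel.
#' @slot Tsteps number of cross-diffusion iterations.
#' @slot kClusters number of clusters for the spectral bipartition.
#' @export
setClass("SNFParams", representation(
    K = "integer", alpha = "numeric", Tsteps = "integer", kClusters = "integer"
), prototype(K = 20L, alpha = 0.5, Tsteps = 15L, kClusters = 2L))

setValidity("SNFParams", function(object) {
    msg <- NULL
    if (object@K < 1L) msg <- c(msg, "K must be >= 1")
    if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
    if (object@Tsteps < 1L) msg <- c(msg, "Tsteps must be >= 1")
    if (object@kClusters < 2L) msg <- c(msg, "kClusters must be >= 2")
    if (is.null(msg)) TRUE else msg
})

#' Construct SNFParams
#'
#' Defaults follow the published subtyping analysis: `K = 20`,
#' `alpha = 0.5`, `Tsteps = 15`, two clusters.
#'
#' @param K neighbourhood size.
#' @param alpha kernel scale.
#' @param Tsteps fusion iterations.
#' @param kClusters number of clusters.
#' @return An [SNFParams-class] object.
#' @export
#' @examples
#' snfParams()
snfParams <- function(K = 20, alpha = 0.5, Tsteps = 15, kClusters = 2) {
    new("SNFParams", K = as.integer(K), alpha = as.numeric(alpha),
        Tsteps = as.integer(Tsteps), kClusters = as.integer(kClusters))
}

#' ModuleSet: co-expression / co-methylation network modules
#'
#' @slot labels named character vector, feature -> module label; `"grey"`
#'   marks unassigned features.
#' @slot eigengenes numeric matrix, samples x modules, the per-module
#'   eigengene profiles.
#' @slot kME numeric matrix, features x modules, correlation of each
#'   feature with each module eigengene (module membership).
#' @slot params list of the network parameters used.
#' @export
setClass("ModuleSet", representation(
    labels = "character", eigengenes = "matrix", kME = "matrix",
    params = "list"
))

setMethod("show", "CohortConfig", function(object) {
    cat("CohortConfig:", object@nSubjectsASD, "ASD /",
        object@nSubjectsControl, "control subjects;",
        sprintf("P(paired regions)=%.2f;", object@pPairedRegions),
        sprintf("frac convergent=%.2f\n", object@fracConvergent))
    cat("  features:   ", paste(sprintf("%s=%d", names(object@nFeatures),
                                        object@nFeatures), collapse = " "), "\n")
    cat("  differential:", paste(sprintf("%s=%d", names(object@nDiffFeatures),
                                         object@nDiffFeatures), collapse = " "), "\n")
    cat("  effect (SD): ", paste(sprintf("%s=%.2g", names(object@effectSize),
                                         object@effectSize), collapse = " "), "\n")
    cat("  seed:", object@seed, "\n")
})

setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation:", length(object@genes), "genes,",
        length(object@probes), "CpG probes,", length(object@peaks),
        "H3K27ac peaks,", nrow(object@eqtl), "eQTL pairs,",
        nrow(object@hic), "Hi-C contacts\n")
})

setMethod("show", "MultiOmicCohort", function(object) {
    cat("MultiOmicCohort with", nrow(object@sampleData), "samples\n")
    for (nm in names(object@layers)) {
        m <- object@layers[[nm]]
        cat(sprintf("  %-7s %5d features x %3d samples\n", nm, nrow(m), ncol(m)))
    }
    dg <- table(object@sampleData$diagnosis)
    cat("  diagnosis:", paste(names(dg), dg, sep = "=", collapse = ", "), "\n")
    if (length(object@truth))
        cat("  ground truth present (synthetic cohort)\n")
})

setMethod("show", "SNFParams", function(object) {
    cat(sprintf("SNFParams: K=%d alpha=%.2f T=%d k=%d\n",
                object@K, object@alpha, object@Tsteps, object@kClusters))
})

setMethod("show", "ModuleSet", function(object) {
    tab <- table(object@labels)
    cat("ModuleSet:", sum(names(tab) != "grey"), "modules over",
        length(object@labels), "features",
        sprintf("(%d grey)\n", sum(object@labels == "grey")))
})
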