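#' @include AllClasses.R genomic-features.R
#' @importFrom stats rnorm runif rbinom rpois plogis setNames
NULL

#' Construct a CohortConfig
#'
#' Defaults reproduce the conditions of the discovery cohort the package
#' models: 30 ASD and 17 control samples observed in all four omics layers
#' (one sample per subject, no missingness), with about two-thirds of ASD
#' subjects in the convergent subtype and a 2-SD standardized shift on the
#' truly differential features of every layer, propagated from a shared
#' subject-level latent severity score. Pairing of frontal/temporal
#' regions, region-discordant convergent subjects, and per-layer
#' missingness are off by default and switched on explicitly where a
#' stage needs them (classifier cascade, mixed-model pairing).
#'
#' @param nSubjectsASD,nSubjectsControl subject counts per diagnosis.
#' @param pPairedRegions probability a subject contributes both frontal
#'   and temporal samples.
#' @param fracConvergent fraction of ASD subjects in the convergent
#'   subtype; count = `round(frac * n)` (banker's rounding).
#' @param fracDiscordant fraction of paired convergent subjects that are
#'   convergent in only one region.
#' @param nFeatures,nDiffFeatures named integer vectors over
#'   [omicLayerNames()].
#' @param effectSize named numeric vector, SD units.
#' @param crossLayerCorr correlation of the propagated severity score
#'   across layers.
#' @param severitySpread SD of the severity score around 1.
#' @param subjectInterceptSd SD of the per-subject, per-feature random
#'   intercept.
#' @param covariateEffects named numeric vector of nuisance effect scales
#'   (SD units) for `age`, `sex`, `region`, `batch`, `bank`, `RIN`,
#'   `CET`, `PMI`, `seqPC1`; each layer receives only the covariates of
#'   its measurement process (see [layerDesigns()]).
#' @param missingness named numeric vector of per-layer missingness
#'   probabilities.
#' @param seed integer seed.
#' @return A [CohortConfig-class] object.
#' @export
#' @examples
#' cohortConfig(seed = 7)
cohortConfig <- function(nSubjectsASD = 30,
                         nSubjectsControl = 17,
                         pPairedRegions = 0,
                         fracConvergent = 2 / 3,
                         fracDiscordant = 0,
                         nFeatures = c(mRNA = 300L, miRNA = 100L,
                                       meth = 250L, acetyl = 250L),
                         nDiffFeatures = c(mRNA = 60L, miRNA = 20L,
                                           meth = 50L, acetyl = 50L),
                         effectSize = c(mRNA = 2, miRNA = 2,
                                        meth = 2, acetyl = 2),
                         crossLayerCorr = 0.98,
                         severitySpread = 0.1,
                         subjectInterceptSd = 0.2,
                         covariateEffects = c(age = 0.015, sex = 0.2,
                                              region = 0.15, batch = 0.2,
                                              bank = 0.15, RIN = 0.1,
                                              CET = 0.3, PMI = 0.1,
                                              seqPC1 = 0.15),
                         missingness = c(mRNA = 0, miRNA = 0,
                                         meth = 0, acetyl = 0),
                         seed = 1L) {
    lay <- omicLayerNames()
    new("CohortConfig",
        nSubjectsASD = as.integer(nSubjectsASD),
        nSubjectsControl = as.integer(nSubjectsControl),
        pPairedRegions = pPairedRegions,
        fracConvergent = fracConvergent,
        fracDiscordant = fracDiscordant,
        nFeatures = setNames(as.integer(nFeatures[lay]), lay),
        nDiffFeatures = setNames(as.integer(nDiffFeatures[lay]), lay),
        effectSize = setNames(as.numeric(effectSize[lay]), lay),
        crossLayerCorr = crossLayerCorr,
        severitySpread = severitySpread,
        subjectInterceptSd = subjectInterceptSd,
        covariateEffects = covariateEffects,
        missingness = setNames(as.numeric(missingness[lay]), lay),
        seed = as.integer(seed))
}

#' Generate a toy genome annotation
#'
#' Tiles a single toy chromosome with stranded genes (alternating
#' strands), scatters CpG probes over promoters and gene bodies with a
#' configurable count distribution (so the two-probe retention filter has
#' both kept and dropped regions to act on), and places H3K27ac peaks: a
#' fraction inside gene promoters and the rest distal, of which fractions
#' carry an eSNP or a Hi-C contact to a promoter within 1 Mb. Contacts
#' carry FDR values; genuine links are drawn below 1% and decoy contacts
#' above it.
#'
#' The first `nDiffFeatures["acetyl"]` peaks are promoter peaks of the
#' first genes, which is what lets [generateCohort()] plant a coupled
#' differential acetylation/expression signal on promoter-linked pairs.
#'
#' @param config a [CohortConfig-class]; gene count =
#'   `nFeatures["mRNA"]`, peak count = `nFeatures["acetyl"]`.
#' @param fracPromoterPeaks fraction of peaks placed inside promoters.
#' @param fracEqtlPeaks fraction of distal peaks given an eSNP link.
#' @param fracHicPeaks fraction of distal peaks given a Hi-C link.
#' @param promoterProbeWeights sampling weights for 0..5 probes per
#'   promoter.
#' @param reseed set the RNG from `config@seed` (default TRUE; the cohort
#'   generator calls this internally with the stream already seeded).
#' @return A [GenomeAnnotation-class] object.
#' @export
generateAnnotations <- function(config,
                                fracPromoterPeaks = 0.4,
                                fracEqtlPeaks = 0.3,
                                fracHicPeaks = 0.3,
                                promoterProbeWeights =
                                    c(0.1, 0.15, 0.25, 0.2, 0.15, 0.15),
                                reseed = TRUE) {
    stopifnot(is(config, "CohortConfig"))
    if (reseed) set.seed(config@seed)
    nGenes <- config@nFeatures[["mRNA"]]
    nPeaks <- config@nFeatures[["acetyl"]]

    # genes tile the chromosome every 40 kb, alternating strands
    spacing <- 40000L
    gstart0 <- 50000L + spacing * (seq_len(nGenes) - 1L)   # 0-based
    gwidth <- as.integer(round(runif(nGenes, 5000, 20000)))
    strand <- rep(c("+", "-"), length.out = nGenes)
    geneIds <- sprintf("g%04d", seq_len(nGenes))
    genesGr <- grangesFromBed("chrT", gstart0, gstart0 + gwidth,
                              strand = strand, gene_id = geneIds,
                              name = sprintf("GENE%d", seq_len(nGenes)))
    prom <- promoterRegions(genesGr)

    # CpG probes: configurable count in each promoter, Poisson(3) in bodies
    nPromProbes <- sample(0:5, nGenes, replace = TRUE,
                          prob = promoterProbeWeights)
    nBodyProbes <- rpois(nGenes, 3)
    probePos <- integer(0)
    for (i in seq_len(nGenes)) {
        if (nPromProbes[i] > 0)
            probePos <- c(probePos, as.integer(round(
                runif(nPromProbes[i], start(prom)[i], end(prom)[i]))))
        if (nBodyProbes[i] > 0)
            probePos <- c(probePos, as.integer(round(
                runif(nBodyProbes[i], start(genesGr)[i], end(genesGr)[i]))))
    }
    probePos <- sort(unique(probePos))
    probesGr <- GRanges("chrT", IRanges(probePos, width = 1L),
                        probe_id = sprintf("cg%06d", seq_along(probePos)))

    # peaks: the first round(frac * n) live inside promoters of the first
    # genes (one per gene), the rest are distal (intergenic)
    nProm <- as.integer(round(fracPromoterPeaks * nPeaks))
    nProm <- min(nProm, nGenes)
    peakStart <- integer(nPeaks); peakEnd <- integer(nPeaks)
    hostGene <- rep(NA_integer_, nPeaks)
    for (k in seq_len(nProm)) {
        g <- k    # promoter peak of gene k
        w <- 800L
        s <- as.integer(round(runif(1, start(prom)[g],
                                    max(start(prom)[g], end(prom)[g] - w))))
        peakStart[k] <- s; peakEnd[k] <- s + w - 1L
        hostGene[k] <- g
    }
    for (k in if (nPeaks > nProm) (nProm + 1L):nPeaks else integer(0)) {
        g <- sample.int(nGenes, 1L)
        # intergenic: downstream gap between gene g and the next gene
        gapStart <- end(genesGr)[g] + 3000L
        gapEnd <- gapStart + 12000L
        w <- as.integer(round(runif(1, 500, 2000)))
        s <- as.integer(round(runif(1, gapStart, gapEnd - w)))
        peakStart[k] <- s; peakEnd[k] <- s + w - 1L
    }
    peaksGr <- GRanges("chrT", IRanges(peakStart, peakEnd),
                       peak_id = sprintf("peak%04d", seq_len(nPeaks)))

    distal <- if (nPeaks > nProm) (nProm + 1L):nPeaks else integer(0)
    tss <- ifelse(strand == "+", start(genesGr), end(genesGr))

    nearbyGene <- function(k) {
        mid <- (peakStart[k] + peakEnd[k]) %/% 2L
        cand <- which(abs(tss - mid) <= 1e6)
        cand[which.min(abs(tss[cand] - mid))]
    }

    # eQTL pairs: eSNP at the peak midpoint, target = nearest gene TSS
    eqtlPeaks <- distal[runif(length(distal)) < fracEqtlPeaks]
    eqtl <- data.frame(snp_id = character(0), chrom = character(0),
                       pos = integer(0), gene_id = character(0))
    if (length(eqtlPeaks)) {
        g <- vapply(eqtlPeaks, nearbyGene, integer(1))
        eqtl <- data.frame(
            snp_id = sprintf("rs%05d", seq_along(eqtlPeaks)),
            chrom = "chrT",
            pos = (peakStart[eqtlPeaks] + peakEnd[eqtlPeaks]) %/% 2L,
            gene_id = geneIds[g], stringsAsFactors = FALSE)
    }

    # Hi-C: anchor A over the peak, anchor B over a nearby promoter;
    # genuine contacts get fdr < 0.01, decoys sit above the threshold
    hicPeaks <- distal[runif(length(distal)) < fracHicPeaks]
    hic <- data.frame(chromA = character(0), startA = integer(0),
                      endA = integer(0), chromB = character(0),
                      startB = integer(0), endB = integer(0),
                      fdr = numeric(0))
    mkContact <- function(k, g, fdr) {
        data.frame(chromA = "chrT",
                   startA = peakStart[k] - 500L, endA = peakEnd[k] + 500L,
                   chromB = "chrT",
                   startB = start(prom)[g] - 500L, endB = end(prom)[g] + 500L,
                   fdr = fdr, stringsAsFactors = FALSE)
    }
    if (length(hicPeaks)) {
        rows <- lapply(hicPeaks, function(k)
            mkContact(k, nearbyGene(k), runif(1, 1e-4, 0.009)))
        hic <- do.call(rbind, rows)
    }
    if (length(distal)) {
        nDecoy <- max(5L, length(hicPeaks) %/% 2L)
        decoyPeaks <- sample(distal, nDecoy, replace = TRUE)
        decoys <- do.call(rbind, lapply(decoyPeaks, function(k)
            mkContact(k, nearbyGene(k), runif(1, 0.02, 0.5))))
        hic <- rbind(hic, decoys)
    }

    new("GenomeAnnotation", genes = genesGr, probes = probesGr,
        peaks = peaksGr, eqtl = eqtl, hic = hic)
}

# standardized covariate design used for signal injection; one column per
# nuisance term, each tagged with the covariate family that scales it.
# Each layer is touched only by the covariates of its own measurement
# process (mirrored by the per-layer model designs in layerDesigns()).
.covariateDesign <- function(meta) {
    X <- cbind(age = as.numeric(scale(meta$age)),
               sex = as.numeric(meta$sex == "M"),
               region = as.numeric(meta$region == "Temporal"),
               batchB2 = as.numeric(meta$batch == "b2"),
               batchB3 = as.numeric(meta$batch == "b3"),
               bank = as.numeric(meta$bank == "bank2"),
               RIN = as.numeric(scale(meta$RIN)),
               CET = as.numeric(scale(meta$CET)),
               PMI = as.numeric(scale(meta$PMI)),
               seqPC1 = as.numeric(scale(meta$seqPC1)))
    fam <- c("age", "sex", "region", "batch", "batch", "bank", "RIN",
             "CET", "PMI", "seqPC1")
    layerFam <- list(
        mRNA = c("age", "sex", "region", "batch", "bank", "RIN", "seqPC1"),
        miRNA = c("age", "sex", "region", "bank", "RIN", "PMI"),
        meth = c("age", "sex", "region", "batch", "bank", "CET"),
        acetyl = c("age", "sex", "region", "bank", "CET"))
    list(X = X, family = fam, layerFamilies = layerFam)
}

#' Generate a synthetic multi-omic cohort with ground truth
#'
#' Draws a cohort under the configured study conditions. Convergent-
#' subtype subjects carry a latent severity score \eqn{z_s \sim N(1,
#' \sigma^2)} propagated to each layer with correlation
#' `crossLayerCorr` and scaled by that layer's `effectSize` into its truly
#' differential features (signs fixed per feature); disparate and control
#' subjects carry \eqn{z_s = 0}. Nuisance covariates (age, sex, region,
#' batch, bank, RIN, CET) are injected additively into differential and
#' non-differential features alike; each subject contributes a per-feature
#' random intercept shared by its two regional samples. Methylation is
#' emitted on the beta scale through a logistic squash of the latent
#' Gaussian values. Differential acetylation peaks are the promoter peaks
#' of differential genes with matching signs, so promoter-linked
#' peak/gene pairs carry a planted positive coupling.
#'
#' The output is byte-identical for a fixed config and seed.
#'
#' @param config a [CohortConfig-class] object.
#' @return A [MultiOmicCohort-class] with ground-truth labels and the toy
#'   [GenomeAnnotation-class].
#' @export
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 1))
#' cohort
generateCohort <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    set.seed(config@seed)
    ann <- generateAnnotations(config, reseed = FALSE)
    lay <- omicLayerNames()

    nA <- config@nSubjectsASD; nC <- config@nSubjectsControl
    subjects <- c(sprintf("sA%03d", seq_len(nA)), sprintf("sC%03d", seq_len(nC)))
    diagnosis <- rep(c("ASD", "Control"), c(nA, nC))
    nConv <- as.integer(round(config@fracConvergent * nA))
    convSubjects <- sample(subjects[seq_len(nA)], nConv)
    subjSubtype <- setNames(ifelse(diagnosis == "Control", "control",
                                   "disparate"), subjects)
    subjSubtype[convSubjects] <- "convergent"

    # subject-level covariates; ASD skews mildly younger with slightly
    # lower RIN (mild, realistic confounding that the adjustment stage
    # must remove without absorbing the subtype signal)
    age <- ifelse(diagnosis == "ASD", runif(nA + nC, 16, 58),
                  runif(nA + nC, 18, 60))
    sex <- sample(c("M", "F"), nA + nC, replace = TRUE, prob = c(0.8, 0.2))
    bank <- sample(c("bank1", "bank2"), nA + nC, replace = TRUE)

    # samples: both regions with prob pPairedRegions, else one at random
    paired <- runif(nA + nC) < config@pPairedRegions
    regionsOf <- lapply(seq_along(subjects), function(i)
        if (paired[i]) c("Frontal", "Temporal")
        else sample(c("Frontal", "Temporal"), 1L))
    meta <- do.call(rbind, lapply(seq_along(subjects), function(i) {
        data.frame(subject_id = subjects[i], diagnosis = diagnosis[i],
                   region = regionsOf[[i]], age = age[i], sex = sex[i],
                   bank = bank[i], stringsAsFactors = FALSE)
    }))
    n <- nrow(meta)
    meta$sample_id <- paste0(meta$subject_id, "_",
                             substr(meta$region, 1, 1))
    meta$batch <- sample(c("b1", "b2", "b3"), n, replace = TRUE)
    meta$RIN <- pmin(9, pmax(5, rnorm(n, 7.05, 0.8)))
    meta$PMI <- pmax(3, rnorm(n, 15, 5))
    meta$CET <- pmin(0.7, pmax(0.2, rnorm(n, 0.45, 0.08)))
    meta$seqPC1 <- rnorm(n)
    meta <- meta[, c("sample_id", "subject_id", "diagnosis", "region",
                     "age", "sex", "bank", "batch", "RIN", "PMI", "CET",
                     "seqPC1")]

    # region-discordant convergent subjects: convergent in one region only
    sampleSubtype <- setNames(subjSubtype[meta$subject_id], meta$sample_id)
    pairedConv <- subjects[paired & subjSubtype[subjects] == "convergent"]
    nDisc <- as.integer(round(config@fracDiscordant * length(pairedConv)))
    discSubjects <- if (nDisc > 0) sample(pairedConv, nDisc) else character(0)
    discOff <- character(0)
    for (s in discSubjects) {
        off <- sample(meta$sample_id[meta$subject_id == s], 1L)
        sampleSubtype[off] <- "disparate"
        discOff <- c(discOff, off)
    }

    # latent severity: subject level, then propagated per layer
    zSubj <- setNames(ifelse(subjSubtype == "convergent",
                             rnorm(length(subjects), 1, config@severitySpread),
                             0), subjects)
    rho <- config@crossLayerCorr
    zLayer <- sapply(lay, function(l) {
        e <- rnorm(length(subjects), 0, config@severitySpread)
        ifelse(subjSubtype == "convergent",
               1 + rho * (zSubj - 1) + sqrt(1 - rho^2) * e, 0)
    })
    rownames(zLayer) <- subjects
    # per-sample severity; discordant samples carry none
    zSample <- zLayer[meta$subject_id, , drop = FALSE]
    rownames(zSample) <- meta$sample_id
    zSample[sampleSubtype[meta$sample_id] != "convergent", ] <- 0

    des <- .covariateDesign(meta)
    covScale <- config@covariateEffects[des$family]
    covScale[is.na(covScale)] <- 0

    featNames <- list(
        mRNA = ann@genes$gene_id,
        miRNA = sprintf("miR%04d", seq_len(config@nFeatures[["miRNA"]])),
        meth = paste0("prom_", ann@genes$gene_id[
            seq_len(config@nFeatures[["meth"]])]),
        acetyl = ann@peaks$peak_id)
    baselineMean <- c(mRNA = 6, miRNA = 8, meth = 0, acetyl = 4)
    baselineSd <- c(mRNA = 2, miRNA = 2, meth = 1.5, acetyl = 1)

    layers <- list(); diffFeatures <- list()
    mRNASigns <- NULL
    for (l in lay) {
        p <- config@nFeatures[[l]]
        nd <- config@nDiffFeatures[[l]]
        fn <- featNames[[l]]
        signs <- sample(c(-1, 1), nd, replace = TRUE)
        if (l == "mRNA") mRNASigns <- signs
        if (l == "acetyl" && !is.null(mRNASigns)) {
            # promoter peaks of differential genes share the gene's sign
            nShared <- min(nd, config@nDiffFeatures[["mRNA"]])
            signs[seq_len(nShared)] <- mRNASigns[seq_len(nShared)]
        }
        diffIdx <- seq_len(nd)    # differential features are the first nd
        diffFeatures[[l]] <- data.frame(feature = fn[diffIdx], sign = signs,
                                        stringsAsFactors = FALSE)
        baseline <- rnorm(p, baselineMean[[l]], baselineSd[[l]])
        layerScale <- covScale *
            (des$family %in% des$layerFamilies[[l]])
        B <- matrix(rnorm(p * ncol(des$X)) * rep(layerScale, each = p), p)
        subjInt <- matrix(rnorm(p * length(subjects),
                                0, config@subjectInterceptSd),
                          p, dimnames = list(fn, subjects))
        M <- baseline +
            B %*% t(des$X) +
            subjInt[, meta$subject_id, drop = FALSE] +
            matrix(rnorm(p * n), p)
        M[diffIdx, ] <- M[diffIdx, ] + config@effectSize[[l]] *
            outer(signs, zSample[, l])
        dimnames(M) <- list(fn, meta$sample_id)
        if (l == "meth") M <- plogis(M)
        layers[[l]] <- M
    }

    # per-layer missingness by sample
    for (l in lay) {
        keep <- runif(n) >= config@missingness[[l]]
        kept <- meta$sample_id[keep]
        for (dg in c("ASD", "Control"))
            if (!any(meta$diagnosis[keep] == dg))
                stop("layer '", l, "' would have 0 observed ", dg,
                     " samples; rejecting config")
        layers[[l]] <- layers[[l]][, kept, drop = FALSE]
    }

    truth <- list(subject_subtype = subjSubtype,
                  sample_subtype = sampleSubtype,
                  diff_features = diffFeatures,
                  severity = zSubj,
                  discordant_subjects = discSubjects,
                  discordant_samples = discOff)
    new("MultiOmicCohort",
        layers = SimpleList(layers),
        sampleData = DataFrame(meta),
        truth = truth,
        annotation = ann)
}

#' Write a cohort bundle to disk
#'
#' Serializes the external representation: one TSV matrix per layer
#' (features x samples), the sample metadata, the ground-truth labels, and
#' the annotation as BED (probes, peaks), a 6-column gene table, an eQTL
#' table, and a Hi-C contact table. All interval files use 0-based
#' half-open coordinates.
#'
#' @param cohort a [MultiOmicCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (l in layerNames(cohort))
        writeOmicsMatrix(omicLayer(cohort, l),
                         file.path(dir, paste0(l, ".tsv")))
    utils::write.table(as.data.frame(sampleData(cohort)),
                       file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tr <- trueLabels(cohort)
    if (length(tr)) {
        truthDf <- data.frame(sample_id = names(tr$sample_subtype),
                              subtype = unname(tr$sample_subtype))
        utils::write.table(truthDf, file.path(dir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ann <- annotation(cohort)
    if (!is.null(ann)) {
        pr <- probes(ann); mcols(pr)$name <- pr$probe_id
        pk <- peaks(ann); mcols(pk)$name <- pk$peak_id
        writeBed6(pr, file.path(dir, "probes.bed"))
        writeBed6(pk, file.path(dir, "peaks.bed"))
        writeGeneTable(genes(ann), file.path(dir, "genes.tsv"))
        writeEqtlTable(eqtlPairs(ann), file.path(dir, "eqtl.tsv"))
        writeHicTable(hicContacts(ann), file.path(dir, "hic.tsv"))
    }
    invisible(dir)
}
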