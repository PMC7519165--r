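#' @include AllClasses.R genomic-features.R
#' @importFrom stats lm
NULL

.peakMid <- function(pk) (start(pk) + end(pk)) %/% 2L

.tssOf <- function(genes) ifelse(strand(genes) == "+",
                                 start(genes), end(genes))

#' Link H3K27ac peaks to cognate genes
#'
#' Implements the evidence schema of the acetylation analysis: a peak
#' overlapping a gene promoter (2 kb upstream of the TSS) is assigned to
#' that proximal gene; a peak outside all promoters is assigned distally
#' by (i) eQTL evidence when an eSNP lies within the peak, and (ii) Hi-C
#' evidence when a contact at FDR < `fdrThreshold` has one anchor
#' overlapping the peak and the other anchor overlapping the gene's
#' promoter (either orientation). All distal linkages are retained even
#' when eQTL and Hi-C disagree. Contacts whose promoter-side anchor
#' overlaps no promoter are skipped and counted in the `log` attribute.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param evidence subset of `c("promoter", "eqtl", "hic")`.
#' @param fdrThreshold Hi-C interaction FDR threshold (default 0.01,
#'   strict).
#' @return `data.frame` with `peak_id`, `gene_id`, `evidence`,
#'   `distance` (peak midpoint to TSS); attribute `log` holds skip
#'   counts.
#' @export
linkPeaksToGenes <- function(ann, evidence = c("promoter", "eqtl", "hic"),
                             fdrThreshold = 0.01) {
    pk <- peaks(ann); gn <- genes(ann)
    prom <- promoterRegions(gn)
    tss <- .tssOf(gn)
    mids <- .peakMid(pk)
    dist2gene <- function(pi, gi) abs(mids[pi] - tss[gi])
    links <- list()
    log <- c(skipped_contacts = 0L)

    ovProm <- findOverlaps(pk, prom, ignore.strand = TRUE)
    promPeaks <- unique(queryHits(ovProm))
    if ("promoter" %in% evidence && length(ovProm))
        links$promoter <- data.frame(
            peak_id = pk$peak_id[queryHits(ovProm)],
            gene_id = gn$gene_id[subjectHits(ovProm)],
            evidence = "promoter",
            distance = dist2gene(queryHits(ovProm), subjectHits(ovProm)),
            stringsAsFactors = FALSE)

    distalIdx <- setdiff(seq_along(pk), promPeaks)
    if ("eqtl" %in% evidence && nrow(eqtlPairs(ann))) {
        eq <- eqtlPairs(ann)
        snps <- GRanges(eq$chrom, IRanges(eq$pos, width = 1L))
        ovSnp <- findOverlaps(snps, pk[distalIdx], ignore.strand = TRUE)
        if (length(ovSnp)) {
            pi <- distalIdx[subjectHits(ovSnp)]
            gi <- match(eq$gene_id[queryHits(ovSnp)], gn$gene_id)
            ok <- !is.na(gi)
            links$eqtl <- data.frame(
                peak_id = pk$peak_id[pi[ok]], gene_id = gn$gene_id[gi[ok]],
                evidence = "eqtl", distance = dist2gene(pi[ok], gi[ok]),
                stringsAsFactors = FALSE)
        }
    }
    if ("hic" %in% evidence && nrow(hicContacts(ann))) {
        hc <- hicContacts(ann)
        hc <- hc[hc$fdr < fdrThreshold, , drop = FALSE]
        src <- if ("source" %in% names(hc)) hc$source else "bulk"
        if (nrow(hc)) {
            aA <- GRanges(hc$chromA, IRanges(hc$startA, hc$endA))
            aB <- GRanges(hc$chromB, IRanges(hc$startB, hc$endB))
            rows <- list()
            for (orient in 1:2) {
                peakA <- if (orient == 1) aA else aB
                promA <- if (orient == 1) aB else aA
                ovP <- findOverlaps(peakA, pk[distalIdx],
                                    ignore.strand = TRUE)
                ovG <- findOverlaps(promA, prom, ignore.strand = TRUE)
                for (ci in unique(queryHits(ovP))) {
                    pis <- distalIdx[subjectHits(ovP)[queryHits(ovP) == ci]]
                    gis <- subjectHits(ovG)[queryHits(ovG) == ci]
                    if (!length(gis)) {
                        log["skipped_contacts"] <-
                            log["skipped_contacts"] + 1L
                        next
                    }
                    grid <- expand.grid(pi = pis, gi = gis)
                    rows[[length(rows) + 1L]] <- data.frame(
                        peak_id = pk$peak_id[grid$pi],
                        gene_id = gn$gene_id[grid$gi],
                        evidence = paste0("hic_",
                                          rep(src, length.out = nrow(hc))[ci]),
                        distance = dist2gene(grid$pi, grid$gi),
                        stringsAsFactors = FALSE)
                }
            }
            if (length(rows)) links$hic <- do.call(rbind, rows)
        }
    }
    out <- do.call(rbind, c(links, list(make.row.names = FALSE)))
    if (is.null(out))
        out <- data.frame(peak_id = character(0), gene_id = character(0),
                          evidence = character(0), distance = integer(0))
    out <- unique(out[order(out$peak_id, out$gene_id, out$evidence), ])
    rownames(out) <- NULL
    attr(out, "log") <- log
    out
}

#' All peak-gene pairs within a distance window
#'
#' The baseline pairing used to show that unselected proximity alone
#' carries little signal: every (peak, gene) pair with
#' `|peak midpoint - TSS| <= window` (default 1 Mb).
#'
#' @param pk `GRanges` of peaks with `peak_id`.
#' @param gn stranded `GRanges` of genes with `gene_id`.
#' @param window distance window in bp.
#' @return `data.frame` with `peak_id`, `gene_id`, `distance`.
#' @export
baselineWindowPairs <- function(pk, gn, window = 1e6) {
    mids <- .peakMid(pk)
    tss <- .tssOf(gn)
    sameChr <- outer(as.character(seqnames(pk)),
                     as.character(seqnames(gn)), "==")
    d <- abs(outer(mids, tss, "-"))
    hit <- which(sameChr & d <= window, arr.ind = TRUE)
    out <- data.frame(peak_id = pk$peak_id[hit[, 1]],
                      gene_id = gn$gene_id[hit[, 2]],
                      distance = d[hit], stringsAsFactors = FALSE)
    out[order(out$peak_id, out$gene_id), , drop = FALSE]
}

#' Correlate differential acetylation with differential expression
#'
#' Over a set of peak-gene links, the Pearson correlation of the two
#' differential effect estimates, with the p-value from the slope test of
#' the linear model `expression change ~ acetylation change`.
#'
#' @param diffAcetyl,diffExpr differential tables ([differentialLMM()])
#'   keyed by `feature_id` (peak IDs / gene IDs).
#' @param links `data.frame` with `peak_id` and `gene_id` columns.
#' @return list with `R`, `p`, `n`, and `pairs` (per-pair table with both
#'   estimates and their signs).
#' @export
correlateDiffSignals <- function(diffAcetyl, diffExpr, links) {
    pairs <- unique(links[, c("peak_id", "gene_id")])
    a <- diffAcetyl$estimate[match(pairs$peak_id, diffAcetyl$feature_id)]
    e <- diffExpr$estimate[match(pairs$gene_id, diffExpr$feature_id)]
    ok <- !is.na(a) & !is.na(e)
    if (sum(ok) < 3L) stop("fewer than 3 linked pairs with both statistics")
    pairs <- pairs[ok, , drop = FALSE]
    pairs$acetyl_estimate <- a[ok]
    pairs$expr_estimate <- e[ok]
    pairs$acetyl_sign <- sign(pairs$acetyl_estimate)
    pairs$expr_sign <- sign(pairs$expr_estimate)
    fit <- lm(pairs$expr_estimate ~ pairs$acetyl_estimate)
    list(R = cor(pairs$acetyl_estimate, pairs$expr_estimate),
         p = summary(fit)$coefficients[2, 4],
         n = nrow(pairs), pairs = pairs)
}

#' Contributory versus compensatory quadrant calls
#'
#' Classifies each linked pair by the signs of its acetylation and
#' expression changes (quadrants `up/up`, `up/down`, `down/up`,
#' `down/down`, acetylation sign first). Matching signs mean the
#' acetylation change is contributory to the expression change; opposing
#' signs mean it is compensatory. Pairs with a zero estimate are skipped
#' and counted in the `skipped` attribute.
#'
#' @param pairs per-pair table from [correlateDiffSignals()] (columns
#'   `acetyl_estimate`, `expr_estimate`).
#' @return `data.frame` with `peak_id`, `gene_id`, `acetyl_sign`,
#'   `expr_sign`, `quadrant`, `call`.
#' @export
quadrantCalls <- function(pairs) {
    zero <- pairs$acetyl_estimate == 0 | pairs$expr_estimate == 0
    out <- pairs[!zero, , drop = FALSE]
    dirA <- ifelse(out$acetyl_estimate > 0, "up", "down")
    dirE <- ifelse(out$expr_estimate > 0, "up", "down")
    res <- data.frame(peak_id = out$peak_id, gene_id = out$gene_id,
                      acetyl_sign = sign(out$acetyl_estimate),
                      expr_sign = sign(out$expr_estimate),
                      quadrant = paste(dirA, dirE, sep = "/"),
                      call = ifelse(dirA == dirE, "contributory",
                                    "compensatory"),
                      stringsAsFactors = FALSE)
    attr(res, "skipped") <- sum(zero)
    res
}

#' Heritability-partition annotation intervals
#'
#' Expands features into the genomic intervals used for partitioned
#' heritability: each gene body +/- 10 kb (`mode = "gene"`) or each
#' H3K27ac peak +/- 1 kb (`mode = "peak"`), clamped at the chromosome
#' start; overlapping expanded intervals are merged and the result is
#' sorted.
#'
#' @param gr `GRanges` of gene bodies or peaks.
#' @param mode `"gene"` or `"peak"`.
#' @return merged, sorted `GRanges`.
#' @export
heritabilityAnnotations <- function(gr, mode = c("gene", "peak")) {
    mode <- match.arg(mode)
    pad <- if (mode == "gene") 10000L else 1000L
    out <- gr
    start(out) <- pmax(1L, start(gr) - pad)
    end(out) <- end(gr) + pad
    sort(reduce(out, ignore.strand = TRUE), ignore.strand = TRUE)
}
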