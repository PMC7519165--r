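#' @include AllClasses.R
#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

# Internal convention: all GRanges are 1-based closed (Bioconductor).
# External TSV/BED interfaces use 0-based half-open coordinates (BED
# convention); conversion happens only in the readers/writers and in the
# `fromBed`/`toBed` helpers below, so there is a single boundary where
# off-by-one errors could live.

#' Build a GRanges from 0-based half-open coordinates
#'
#' Convenience constructor used throughout the package's I/O layer and
#' tests: takes BED-style `[start, end)` 0-based coordinates and returns
#' the equivalent 1-based closed `GRanges`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open interval bounds (`start < end`).
#' @param strand strand characters (`"+"`, `"-"` or `"*"`); BED's `"."`
#'   is accepted and mapped to `"*"`.
#' @param ... further vectors stored as metadata columns.
#' @return A `GRanges`.
#' @export
#' @examples
#' grangesFromBed("chr1", 0, 10, id = "x")   # 1-based [1,10]
grangesFromBed <- function(chrom, start, end, strand = "*", ...) {
    stopifnot(all(start >= 0), all(start < end))
    strand <- ifelse(strand == ".", "*", strand)
    GRanges(chrom, IRanges(start + 1L, end), strand = strand, ...)
}

#' Extract 0-based half-open coordinates from a GRanges
#'
#' @param gr a `GRanges`.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open) plus any metadata columns.
#' @export
grangesToBed <- function(gr) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     strand = as.character(strand(gr)),
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(mcols(gr)))
}

#' Half-open interval overlap test
#'
#' TRUE iff the two intervals are on the same chromosome and intersect
#' under half-open semantics: `a.start < b.end && b.start < a.end` on the
#' 0-based scale (equivalently, closed-interval intersection of the
#' 1-based representation). Vectorized over pairs.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return logical vector.
#' @export
#' @examples
#' a <- grangesFromBed("chr1", 0, 10)
#' b <- grangesFromBed("chr1", 10, 20)
#' intervalsOverlap(a, b)   # FALSE: [0,10) and [10,20) only touch
intervalsOverlap <- function(a, b) {
    if (length(a) == 1L) a <- rep(a, length(b))
    if (length(b) == 1L) b <- rep(b, length(a))
    stopifnot(length(a) == length(b))
    as.character(seqnames(a)) == as.character(seqnames(b)) &
        start(a) <= end(b) & start(b) <= end(a)
}

#' Promoter intervals of stranded genes
#'
#' The promoter is the 2 kb window immediately upstream of the
#' transcription start site: for a `+`-strand gene `[TSS-2000, TSS)` and
#' for a `-`-strand gene `[TSS, TSS+2000)` in 0-based half-open
#' coordinates, clamped at the chromosome start. Genes without a strand
#' are rejected, since the TSS is undefined.
#'
#' @param genes stranded `GRanges` of gene bodies (TSS..TES).
#' @param upstream promoter width in bp upstream of the TSS.
#' @return `GRanges` of promoters, carrying the genes' metadata.
#' @export
#' @examples
#' g <- grangesFromBed("chr1", 10000, 20000, strand = "+", gene_id = "g1")
#' grangesToBed(promoterRegions(g))   # promoter [8000, 10000)
promoterRegions <- function(genes, upstream = 2000L) {
    if (any(strand(genes) == "*"))
        stop("promoter derivation requires stranded genes; found strand '*'")
    prom <- promoters(genes, upstream = upstream, downstream = 0L)
    # clamp at the chromosome start (position 1 in 1-based coordinates)
    start(prom) <- pmax(start(prom), 1L)
    end(prom) <- pmax(end(prom), 1L)
    prom
}

#' Gene-body intervals
#'
#' The gene body runs from the TSS to the transcription end site, i.e. it
#' is the gene range itself.
#'
#' @param genes `GRanges` of genes.
#' @return `GRanges`.
#' @export
geneBodyRegions <- function(genes) genes

#' Collapse CpG probe methylation onto regions
#'
#' Averages probe-level beta values over the probes falling in each region
#' (promoter or gene body). Regions covered by fewer than `minProbes`
#' probes are dropped; the published analysis keeps only promoters/gene
#' bodies with two or more CpG probes. A probe overlapping two regions
#' contributes to both. Missing probe values are averaged over the
#' non-missing probes (with a message); a region whose probes are all
#' missing for a sample propagates `NA`.
#'
#' @param beta numeric matrix, probes x samples; rownames are probe IDs
#'   matching `probes$probe_id`.
#' @param probes `GRanges` of probe positions with a `probe_id` column.
#' @param regions `GRanges` of target regions; names (or a `region_id`
#'   column) identify output rows.
#' @param minProbes minimum number of member probes for a region to be
#'   retained (default 2).
#' @return numeric matrix, retained regions x samples.
#' @export
collapseProbes <- function(beta, probes, regions, minProbes = 2L) {
    stopifnot(is.matrix(beta), !is.null(rownames(beta)))
    rid <- if (!is.null(mcols(regions)$region_id)) mcols(regions)$region_id
           else names(regions)
    if (is.null(rid)) stop("regions must be named or carry 'region_id'")
    pid <- mcols(probes)$probe_id
    keep <- pid %in% rownames(beta)
    probes <- probes[keep]; pid <- pid[keep]
    ov <- findOverlaps(probes, regions, ignore.strand = TRUE)
    cnt <- tabulate(subjectHits(ov), nbins = length(regions))
    retained <- which(cnt >= minProbes)
    if (!length(retained)) {
        warning("no region retained at minProbes = ", minProbes)
        out <- matrix(numeric(0), 0, ncol(beta),
                      dimnames = list(NULL, colnames(beta)))
        return(out)
    }
    if (anyNA(beta[pid[queryHits(ov)], , drop = FALSE]))
        message("missing probe values: region means use non-missing probes")
    out <- matrix(NA_real_, length(retained), ncol(beta),
                  dimnames = list(rid[retained], colnames(beta)))
    for (k in seq_along(retained)) {
        r <- retained[k]
        members <- pid[queryHits(ov)[subjectHits(ov) == r]]
        sub <- beta[members, , drop = FALSE]
        out[k, ] <- colMeans(sub, na.rm = TRUE)
    }
    out[is.nan(out)] <- NA_real_
    out
}

# ---- readers / writers (0-based half-open TSV and BED at the boundary) ----

#' Read and write BED6 files
#'
#' Thin wrappers over `rtracklayer`'s BED support. `writeBed6` always
#' emits six columns (chrom, start, end, name, score, strand) so that a
#' write/read cycle round-trips exactly.
#'
#' @param path file path.
#' @param gr a `GRanges`; its `name` metadata column (or names) populates
#'   BED column 4, `score` populates column 5 (0 if absent).
#' @return `readBed6` returns a `GRanges` with `name` and `score` columns.
#' @export
readBed6 <- function(path) {
    rtracklayer::import(path, format = "BED")
}

#' @rdname readBed6
#' @export
writeBed6 <- function(gr, path) {
    if (is.null(mcols(gr)$name))
        mcols(gr)$name <- if (!is.null(names(gr))) names(gr)
                          else paste0("feature_", seq_along(gr))
    if (is.null(mcols(gr)$score)) mcols(gr)$score <- 0L
    mcols(gr) <- mcols(gr)[, c("name", "score")]
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read and write the 6-column gene table
#'
#' Tab-separated with header `gene_id, chrom, start, end, strand, name`;
#' coordinates 0-based half-open.
#'
#' @param path file path.
#' @param genes `GRanges` with `gene_id` and `name` metadata.
#' @return `readGeneTable` returns a `GRanges`.
#' @export
readGeneTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    grangesFromBed(df$chrom, df$start, df$end, strand = df$strand,
                   gene_id = df$gene_id, name = df$name)
}

#' @rdname readGeneTable
#' @export
writeGeneTable <- function(genes, path) {
    bed <- grangesToBed(genes)
    df <- data.frame(gene_id = bed$gene_id, chrom = bed$chrom,
                     start = bed$start, end = bed$end,
                     strand = bed$strand, name = bed$name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write eQTL pair tables
#'
#' Tab-separated with header `snp_id, chrom, pos, gene_id`; `pos` is the
#' 0-based position of the eSNP (stored internally 1-based).
#'
#' @param path file path.
#' @param eqtl `data.frame` in the internal (1-based `pos`) convention.
#' @return `readEqtlTable` returns the internal `data.frame`.
#' @export
readEqtlTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$pos <- df$pos + 1L
    df
}

#' @rdname readEqtlTable
#' @export
writeEqtlTable <- function(eqtl, path) {
    out <- eqtl
    out$pos <- out$pos - 1L
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write Hi-C contact tables
#'
#' Tab-separated with header
#' `chromA, startA, endA, chromB, startB, endB, fdr`; anchors 0-based
#' half-open (stored internally 1-based closed).
#'
#' @param path file path.
#' @param hic `data.frame` in the internal convention.
#' @return `readHicTable` returns the internal `data.frame`.
#' @export
readHicTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$startA <- df$startA + 1L
    df$startB <- df$startB + 1L
    df
}

#' @rdname readHicTable
#' @export
writeHicTable <- function(hic, path) {
    out <- hic
    out$startA <- out$startA - 1L
    out$startB <- out$startB - 1L
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write an omics matrix as TSV
#'
#' Rows are features, columns samples; the header row carries the sample
#' IDs and the first column (`feature_id`) the feature IDs.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @return `readOmicsMatrix` returns a numeric matrix.
#' @export
writeOmicsMatrix <- function(m, path) {
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeOmicsMatrix
#' @export
readOmicsMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}
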