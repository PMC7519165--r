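# hand-built annotation: 3 genes, mixed promoter/distal peaks, eQTL + Hi-C
toyAnnotation <- function() {
    genes <- grangesFromBed("chr1", c(100000, 300000, 2000000),
                            c(110000, 320000, 2010000),
                            strand = c("+", "-", "+"),
                            gene_id = c("gA", "gB", "gC"),
                            name = c("A", "B", "C"))
    # promoters: gA [98000,100000); gB [320000,322000); gC [1998000,2000000)
    peaks <- grangesFromBed("chr1",
        c(99000,    150000,  321000, 500000,  1999000, 150500),
        c(99500,    151000,  321400, 500800,  1999400, 151200),
        peak_id = paste0("p", 1:6))
    eqtl <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 150500L,
                       gene_id = "gA", stringsAsFactors = FALSE)
    hic <- data.frame(chromA = "chr1", startA = c(499900L, 499900L, 150000L),
                      endA = c(501000L, 501000L, 151500L),
                      chromB = "chr1", startB = c(319900L, 319900L, 400000L),
                      endB = c(322500L, 322500L, 401000L),
                      fdr = c(0.005, 0.02, 0.004), stringsAsFactors = FALSE)
    new("GenomeAnnotation", genes = genes, probes = GRanges(),
        peaks = peaks, eqtl = eqtl, hic = hic)
}

test_that("peak-to-gene linkage applies the evidence schema", {
    ann <- toyAnnotation()
    links <- linkPeaksToGenes(ann)
    # p1 in gA promoter, p3 in gB promoter, p5 in gC promoter
    prom <- links[links$evidence == "promoter", ]
    expect_setequal(paste(prom$peak_id, prom$gene_id),
                    c("p1 gA", "p3 gB", "p5 gC"))
    # the eSNP (1-based 150500) sits in p2 [150001,151000] but not p6
    # [150501,151200]
    eq <- links[links$evidence == "eqtl", ]
    expect_equal(paste(eq$peak_id, eq$gene_id), "p2 gA")
    # Hi-C: contact 1 (fdr 0.005) links p4 to gB; contact 2 (fdr 0.02 >= 1%)
    # does not; contact 3 touches p2/p6 but its other anchor hits no promoter
    hic <- links[grepl("^hic", links$evidence), ]
    expect_equal(paste(hic$peak_id, hic$gene_id), "p4 gB")
    expect_gte(attr(links, "log")[["skipped_contacts"]], 1)
    # promoter peaks get no distal evidence
    expect_false(any(links$peak_id %in% c("p1", "p3", "p5") &
                     links$evidence != "promoter"))
})

test_that("linkage matches a brute-force triple-overlap oracle", {
    set.seed(44)
    for (rep in 1:10) {
        cfg <- cohortConfig(nFeatures = c(mRNA = 40L, miRNA = 10L,
                                          meth = 30L, acetyl = 60L),
                            nDiffFeatures = c(mRNA = 10L, miRNA = 4L,
                                              meth = 8L, acetyl = 12L),
                            seed = 400 + rep)
        ann <- generateAnnotations(cfg)
        links <- linkPeaksToGenes(ann)
        gb <- grangesToBed(genes(ann)); pb <- grangesToBed(peaks(ann))
        promB <- grangesToBed(promoterRegions(genes(ann)))
        ov <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
        # oracle: promoter links by exhaustive double loop
        got <- links[links$evidence == "promoter", c("peak_id", "gene_id")]
        want <- do.call(rbind, lapply(seq_len(nrow(pb)), function(i) {
            hit <- which(ov(pb$start[i], pb$end[i], promB$start, promB$end))
            if (length(hit)) data.frame(peak_id = pb$peak_id[i],
                                        gene_id = promB$gene_id[hit])
        }))
        expect_setequal(paste(got$peak_id, got$gene_id),
                        paste(want$peak_id, want$gene_id))
        # oracle: hic links (fdr < 0.01, either anchor orientation)
        hc <- hicContacts(ann)
        promPeaks <- unique(want$peak_id)
        wantH <- character(0)
        for (ci in which(hc$fdr < 0.01)) {
            for (orient in 1:2) {
                pa <- if (orient == 1) c(hc$startA[ci], hc$endA[ci])
                      else c(hc$startB[ci], hc$endB[ci])
                pr <- if (orient == 1) c(hc$startB[ci], hc$endB[ci])
                      else c(hc$startA[ci], hc$endA[ci])
                pks <- pb$peak_id[ov(pb$start, pb$end, pa[1] - 1, pa[2]) &
                                  !(pb$peak_id %in% promPeaks)]
                gns <- promB$gene_id[ov(promB$start, promB$end,
                                        pr[1] - 1, pr[2])]
                if (length(pks) && length(gns))
                    wantH <- c(wantH, as.vector(outer(pks, gns, paste)))
            }
        }
        gotH <- links[grepl("^hic", links$evidence), ]
        expect_setequal(paste(gotH$peak_id, gotH$gene_id), unique(wantH))
        # row-order invariance of the evidence table
        links2 <- linkPeaksToGenes(ann)
        expect_identical(links[order(links$peak_id, links$gene_id,
                                     links$evidence), 1:3],
                         links2[order(links2$peak_id, links2$gene_id,
                                      links2$evidence), 1:3])
    }
})

test_that("baseline window pairs respect the 1 Mb boundary exactly", {
    genes <- grangesFromBed("chr1", 2000000, 2010000, strand = "+",
                            gene_id = "g", name = "g")   # TSS at 2000000
    # peak midpoints at TSS - 999000, TSS - 1000001, TSS + 1000000
    peaks <- grangesFromBed("chr1",
        c(1000500, 999499, 2999500), c(1001500, 1000499, 3000500),
        peak_id = c("near", "far", "edge"))
    pairs <- baselineWindowPairs(peaks, genes)
    expect_setequal(pairs$peak_id, c("near", "edge"))
    # exhaustive oracle on a toy genome
    cfg <- cohortConfig(nFeatures = c(mRNA = 30L, miRNA = 10L,
                                      meth = 20L, acetyl = 40L),
                        nDiffFeatures = c(mRNA = 5L, miRNA = 2L,
                                          meth = 4L, acetyl = 6L),
                        seed = 9)
    ann <- generateAnnotations(cfg)
    pairs2 <- baselineWindowPairs(peaks(ann), genes(ann))
    pb <- grangesToBed(peaks(ann)); gb <- grangesToBed(genes(ann))
    tss <- ifelse(gb$strand == "+", gb$start + 1, gb$end)   # 1-based TSS
    mid <- (pb$start + 1 + pb$end) %/% 2
    cnt <- 0
    for (i in seq_len(nrow(pb))) for (j in seq_len(nrow(gb)))
        if (abs(mid[i] - tss[j]) <= 1e6) cnt <- cnt + 1
    expect_equal(nrow(pairs2), cnt)
    # every distal evidence link is inside the window set
    links <- linkPeaksToGenes(ann)
    distal <- links[links$evidence != "promoter", ]
    expect_true(all(paste(distal$peak_id, distal$gene_id) %in%
                    paste(pairs2$peak_id, pairs2$gene_id)))
})

test_that("differential coupling correlation behaves on planted signals", {
    set.seed(2)
    mk <- function(est, ids) data.frame(feature_id = ids, estimate = est,
                                        se = 1, p = 0.5, q = 0.5)
    ids <- paste0("x", 1:40)
    a <- rnorm(40)
    links <- data.frame(peak_id = ids, gene_id = ids)
    # pairs on y = x: R exactly 1
    out <- suppressWarnings(correlateDiffSignals(mk(a, ids), mk(a, ids),
                                                 links))
    expect_equal(out$R, 1)
    # sign-flipped coupling: R < 0
    out2 <- correlateDiffSignals(mk(a, ids), mk(-a + rnorm(40, 0, 0.3), ids),
                                 links)
    expect_lt(out2$R, 0)
    expect_error(correlateDiffSignals(mk(a[1:2], ids[1:2]),
                                      mk(a[1:2], ids[1:2]),
                                      links[1:2, ]), "3 linked")
})

test_that("quadrant calls classify contributory vs compensatory pairs", {
    pairs <- data.frame(peak_id = paste0("p", 1:5),
                        gene_id = paste0("g", 1:5),
                        acetyl_estimate = c(1, 1, -1, -1, 0),
                        expr_estimate = c(1, -1, 1, -1, 2))
    qc <- quadrantCalls(pairs)
    expect_equal(nrow(qc), 4)                     # zero-estimate pair skipped
    expect_equal(attr(qc, "skipped"), 1)
    expect_equal(qc$quadrant, c("up/up", "up/down", "down/up", "down/down"))
    expect_equal(qc$call, c("contributory", "compensatory",
                            "compensatory", "contributory"))
})

test_that("planted promoter coupling yields positive R above baseline", {
    cfg <- cohortConfig(seed = 71)
    co <- generateCohort(cfg)
    meta <- as.data.frame(sampleData(co))
    des <- layerDesigns()
    labels <- trueLabels(co)$sample_subtype
    dExpr <- subtypeDifferential(omicLayer(co, "mRNA"), meta, labels,
                                 "convergent", des$mRNA)
    dAcet <- subtypeDifferential(omicLayer(co, "acetyl"), meta, labels,
                                 "convergent", des$acetyl)
    ann <- annotation(co)
    links <- linkPeaksToGenes(ann)
    prom <- links[links$evidence == "promoter", ]
    outProm <- correlateDiffSignals(dAcet, dExpr, prom)
    expect_gt(outProm$n, 50)
    expect_gt(outProm$R, 0)
    expect_lt(outProm$p, 0.05)
    # baseline 1 Mb pairs: weaker correlation than promoter-linked pairs
    base <- baselineWindowPairs(peaks(ann), genes(ann))
    outBase <- correlateDiffSignals(dAcet, dExpr, base)
    expect_gt(abs(outProm$R), abs(outBase$R))
})

test_that("heritability annotation intervals pad, clamp, merge and sort", {
    g <- grangesFromBed("chrT", 100000, 105000, gene_id = "g", name = "g")
    out <- grangesToBed(heritabilityAnnotations(g, "gene"))
    expect_equal(c(out$start, out$end), c(90000, 115000))
    pk <- grangesFromBed("chrT", 500, 800, peak_id = "p")
    out2 <- grangesToBed(heritabilityAnnotations(pk, "peak"))
    expect_equal(c(out2$start, out2$end), c(0, 1800))
    # overlapping expanded peaks merge to one record, sorted output
    pks <- grangesFromBed("chrT", c(9000, 5000, 10500),
                          c(9400, 5400, 10900),
                          peak_id = c("a", "b", "c"))
    out3 <- grangesToBed(heritabilityAnnotations(pks, "peak"))
    expect_equal(nrow(out3), 2)
    expect_equal(out3$start, c(4000, 8000))
    expect_equal(out3$end, c(6400, 11900))
})
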