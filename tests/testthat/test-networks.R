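test_that("bicor is exact on identities and robust to gross outliers", {
    set.seed(6)
    x <- rnorm(20)
    X <- rbind(a = x, b = -x, c = rnorm(20))
    R <- bicorMatrix(X)
    expect_equal(R["a", "a"], 1)
    expect_equal(R["a", "b"], -1, tolerance = 1e-12)
    expect_true(all(R >= -1 & R <= 1))
    expect_true(isSymmetric(R))
    # one gross outlier: bicor stays closer to the clean Pearson than the
    # contaminated Pearson does (robustness, 100 replicates)
    wins <- replicate(100, {
        n <- 20
        u <- rnorm(n); v <- 0.8 * u + rnorm(n, 0, 0.6)
        cleanP <- cor(u, v)
        u2 <- u; v2 <- v; u2[1] <- 10; v2[1] <- -10
        contP <- cor(u2, v2)
        b <- bicorMatrix(rbind(u = u2, v = v2))["u", "v"]
        abs(b - cleanP) < abs(contP - cleanP)
    })
    expect_gt(mean(wins), 0.9)
    # constant feature is an error; zero-MAD falls back to Pearson
    expect_error(bicorMatrix(rbind(k = rep(1, 20), x = x)), "constant")
    Xz <- rbind(z = c(rep(0, 18), 1, 2), x = x)   # median-degenerate
    expect_message(Rz <- bicorMatrix(Xz), "Pearson")
    expect_true(is.finite(Rz["z", "x"]))
})

test_that("signed adjacency and TOM match hand arithmetic", {
    expect_equal(signedAdjacency(matrix(1, 1, 1), 9)[1, 1], 0)  # diag zeroed
    R <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3, 3)
    A <- signedAdjacency(R, 9)
    expect_equal(A[1, 2], 0.5^9)
    expect_equal(A[1, 3], 0)
    expect_equal(A[2, 3], 0.75^9)
    # complete triangle of unit adjacency: TOM = 1 everywhere
    A1 <- matrix(1, 3, 3); diag(A1) <- 0
    T1 <- topologicalOverlap(A1)
    expect_equal(T1[1, 2], 1)
    # isolated pair with weight w: TOM = w
    for (w in c(0.2, 0.7)) {
        A2 <- matrix(0, 4, 4); A2[1, 2] <- A2[2, 1] <- w
        expect_equal(topologicalOverlap(A2)[1, 2], w)
    }
    # brute-force definition on random matrices
    set.seed(8)
    for (rep in 1:100) {
        p <- sample(4:10, 1)
        A <- matrix(runif(p * p), p)
        A <- (A + t(A)) / 2; diag(A) <- 0
        tom <- topologicalOverlap(A)
        i <- sample(p, 1); j <- sample(setdiff(1:p, i), 1)
        k <- rowSums(A)
        want <- (sum(A[i, ] * A[, j]) + A[i, j]) /
                (min(k[i], k[j]) + 1 - A[i, j])
        expect_equal(tom[i, j], want, tolerance = 1e-12)
        expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
        expect_equal(unname(diag(tom)), rep(1, p))
        # identical rows make TOM maximal among that row's entries
    }
})

test_that("consensus TOM reduces to the plain TOM and averages bootstraps", {
    set.seed(10)
    X <- matrix(rnorm(15 * 24), 15, 24,
                dimnames = list(paste0("f", 1:15), paste0("s", 1:24)))
    plain <- topologicalOverlap(signedAdjacency(bicorMatrix(X), 9))
    one <- consensusTOM(X, beta = 9, nBootstraps = 1, resample = FALSE)
    expect_equal(one, plain, tolerance = 1e-12)
    # median over identical TOMs is that TOM
    three <- consensusTOM(X, beta = 9, nBootstraps = 3, resample = FALSE)
    expect_equal(three, plain, tolerance = 1e-12)
    # planted 2-module structure survives the bootstrap median
    f1 <- rnorm(30); f2 <- rnorm(30)
    Xp <- rbind(t(replicate(10, f1 + rnorm(30, 0, 0.4))),
                t(replicate(10, f2 + rnorm(30, 0, 0.4))))
    dimnames(Xp) <- list(paste0("g", 1:20), paste0("t", 1:30))
    ct <- consensusTOM(Xp, beta = 9, nBootstraps = 10, seed = 4)
    within <- mean(c(ct[1:10, 1:10][upper.tri(diag(10))],
                     ct[11:20, 11:20][upper.tri(diag(10))]))
    across <- mean(ct[1:10, 11:20])
    expect_gt(within, 2 * across)
})

test_that("module detection recovers planted blocks and obeys size/merge rules", {
    set.seed(15)
    n <- 40
    f1 <- rnorm(n); f2 <- rnorm(n)
    mk <- function(f, k, noise) t(replicate(k, f * sqrt(1 - noise^2) +
                                               rnorm(n, 0, noise)))
    X <- rbind(mk(f1, 15, 0.6), mk(f2, 15, 0.6))
    dimnames(X) <- list(paste0("f", 1:30), paste0("s", 1:n))
    tom <- consensusTOM(X, beta = 9, nBootstraps = 1, resample = FALSE)
    ms <- detectModules(tom, X, minModuleSize = 10)
    lab <- moduleLabels(ms)
    expect_setequal(unique(lab[1:15]), unique(lab[1:15])[1])  # one block
    expect_equal(length(unique(lab[1:15])), 1L)
    expect_equal(length(unique(lab[16:30])), 1L)
    expect_false(lab[1] == lab[16])
    expect_false(any(lab[1:30] == "grey"))
    # permutation invariance in feature order
    perm <- sample(30)
    ms2 <- detectModules(tom[perm, perm], X[perm, ], minModuleSize = 10)
    agree <- assignmentConcordance(moduleLabels(ms2), lab[perm])
    expect_equal(agree, 1.0)
    # blocks below the minimum size go grey
    expect_warning(ms3 <- detectModules(tom[1:8, 1:8], X[1:8, ],
                                        minModuleSize = 20), "grey")
    expect_true(all(moduleLabels(ms3) == "grey"))
    # near-identical eigengenes merge under the 0.1 threshold
    X4 <- rbind(mk(f1, 12, 0.25), mk(f1, 12, 0.25), mk(f2, 12, 0.5))
    dimnames(X4) <- list(paste0("h", 1:36), paste0("s", 1:n))
    tom4 <- consensusTOM(X4, beta = 9, nBootstraps = 1, resample = FALSE)
    ms4 <- detectModules(tom4, X4, minModuleSize = 8, mergeThreshold = 0.1)
    lab4 <- moduleLabels(ms4)
    expect_equal(length(unique(lab4[1:24])), 1L)   # the twins merged
})

test_that("module eigengene matches an SVD oracle with stable orientation", {
    set.seed(20)
    X <- matrix(rnorm(10 * 25), 10, 25,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:25)))
    eg <- moduleEigengene(X, rownames(X))
    # oracle: first right singular vector of the standardized matrix
    Z <- t(scale(t(X)))
    sv <- svd(Z)
    want <- sv$v[, 1]
    if (want[which.max(abs(want))] < 0) want <- -want
    expect_equal(unname(eg), want, tolerance = 1e-8)
    # identical features: eigengene = that feature standardized (unit
    # norm, up to the documented sample-side orientation)
    Xi <- rbind(a = X[1, ], b = X[1, ])
    egi <- moduleEigengene(Xi, c("a", "b"))
    z1 <- scale(X[1, ])[, 1]
    expect_equal(abs(cor(egi, z1)), 1, tolerance = 1e-10)
    expect_equal(abs(unname(egi)), unname(abs(z1 / sqrt(sum(z1^2)))),
                 tolerance = 1e-8)
    # flipping every feature's sign leaves the eigengene unchanged
    expect_equal(moduleEigengene(-X, rownames(X)), eg, tolerance = 1e-8)
})

test_that("eigengene-trait association finds planted effects, is calibrated", {
    set.seed(30)
    n <- 40
    meta <- toyMeta(n, paired = TRUE, seed = 30)
    egPlanted <- as.numeric(meta$diagnosis == "ASD") + rnorm(n, 0, 0.1)
    eg <- cbind(M1 = egPlanted, M2 = rnorm(n))
    rownames(eg) <- meta$sample_id
    res <- moduleTraitAssociation(eg, meta,
                                  designSpec(fixed = c("diagnosis", "age"),
                                             group = "subject_id"))
    expect_gt(res$estimate[res$feature_id == "M1"], 0)
    expect_lt(res$p[res$feature_id == "M1"], 0.01)
    # null calibration: p-values uniform over 50 seeds (KS at 1%)
    ps <- vapply(1:50, function(s) {
        set.seed(1000 + s)
        egN <- cbind(M = rnorm(n))
        rownames(egN) <- meta$sample_id
        moduleTraitAssociation(egN, meta,
                               designSpec(fixed = c("diagnosis", "age"),
                                          group = "subject_id"))$p
    }, numeric(1))
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
    # constant eigengene is a degenerate fit
    egC <- cbind(M = rep(1, n)); rownames(egC) <- meta$sample_id
    expect_error(moduleTraitAssociation(egC, meta), "degenerate")
})

test_that("hub selection keeps the top quantile with ties included", {
    lab <- setNames(rep("M1", 4), paste0("f", 1:4))
    kme <- matrix(c(0.9, 0.8, 0.7, 0.6), 4, 1,
                  dimnames = list(names(lab), "M1"))
    ms <- new("ModuleSet", labels = lab, eigengenes = matrix(0, 1, 1),
              kME = kme, params = list())
    expect_equal(hubSelection(ms, "M1"), "f1")
    # all equal: all selected
    kme2 <- kme; kme2[] <- 0.5
    ms2 <- new("ModuleSet", labels = lab, eigengenes = matrix(0, 1, 1),
               kME = kme2, params = list())
    expect_setequal(hubSelection(ms2, "M1"), names(lab))
    # 100 members: exactly 25 hubs for distinct kMEs (sort oracle)
    set.seed(2)
    v <- sort(runif(100), decreasing = TRUE)
    lab3 <- setNames(rep("M1", 100), paste0("g", 1:100))
    kme3 <- matrix(v, 100, 1, dimnames = list(names(lab3), "M1"))
    ms3 <- new("ModuleSet", labels = lab3, eigengenes = matrix(0, 1, 1),
               kME = kme3, params = list())
    hubs <- hubSelection(ms3, "M1")
    expect_setequal(hubs, paste0("g", 1:25))
})

test_that("gene-set logistic enrichment detects overlap and is calibrated", {
    bg <- paste0("g", 1:1000)
    set.seed(40)
    s1 <- sample(bg, 120)
    # self-enrichment embedded in a larger background
    eSelf <- genesetEnrichmentLogistic(s1, s1, bg)
    expect_gt(eSelf$oddsRatio, 1)
    expect_lt(eSelf$p, 0.05)
    # disjoint sets covering the background: OR < 1
    half <- bg[1:500]
    eDis <- genesetEnrichmentLogistic(half, setdiff(bg, half), bg)
    expect_lt(eDis$oddsRatio, 1)
    # independent random sets: type-I rate near 5% over 100 replicates
    hits <- replicate(100, {
        a <- sample(bg, 50); b <- sample(bg, 50)
        genesetEnrichmentLogistic(a, b, bg)$p < 0.05
    })
    expect_lt(mean(hits), 0.12)
    expect_error(genesetEnrichmentLogistic(character(0), s1, bg), "empty")
})

test_that("Fisher exact p matches full enumeration on small tables", {
    expect_equal(fisherExact2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
                 tolerance = 1e-12)
    expect_equal(fisherExact2x2(matrix(c(0, 10, 0, 10), 2)), 1)
    # all 2x2 tables with margins <= 15 against the enumeration oracle
    set.seed(50)
    for (rep in 1:200) {
        tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
        expect_equal(fisherExact2x2(tab), bruteFisher(tab),
                     tolerance = 1e-9)
    }
    expect_error(fisherExact2x2(matrix(c(1.5, 1, 1, 1), 2)))
})
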