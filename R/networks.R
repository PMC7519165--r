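#' @include AllClasses.R differential.R
#' @importFrom stats median mad cor hclust cutree as.dist quantile
#'   fisher.test fitted
NULL

#' Biweight midcorrelation matrix
#'
#' Robust correlation between features: each feature is centered at its
#' median and weighted by the Tukey biweight with the standard tuning
#' (`u = (x - med) / (9 * mad)`, weight `(1 - u^2)^2` inside `|u| < 1`),
#' then the weighted vectors are correlated. Features whose MAD is zero
#' (no spread around the median) fall back to Pearson correlation and
#' are flagged with a message; fully constant features are an error.
#'
#' @param X numeric matrix, features x samples (>= 4 samples).
#' @return features x features correlation matrix in \[-1, 1\].
#' @export
bicorMatrix <- function(X) {
    stopifnot(ncol(X) >= 4L)
    sds <- apply(X, 1, sd)
    if (any(sds == 0))
        stop("constant feature(s): correlation undefined for ",
             paste(rownames(X)[sds == 0], collapse = ", "))
    p <- nrow(X)
    Xt <- matrix(0, p, ncol(X), dimnames = dimnames(X))
    madZero <- logical(p)
    for (i in seq_len(p)) {
        x <- X[i, ]
        med <- median(x)
        mx <- median(abs(x - med))
        if (mx == 0) {
            madZero[i] <- TRUE
            v <- x - mean(x)
        } else {
            u <- (x - med) / (9 * mx)
            w <- (1 - u^2)^2 * (abs(u) < 1)
            v <- (x - med) * w
        }
        Xt[i, ] <- v / sqrt(sum(v^2))
    }
    if (any(madZero))
        message(sum(madZero), " feature(s) with zero MAD used Pearson fallback")
    R <- tcrossprod(Xt)
    R[R > 1] <- 1; R[R < -1] <- -1
    diag(R) <- 1
    R
}

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta` with a zero diagonal, mapping the
#' correlation range \[-1, 1\] onto \[0, 1\] so that strong negative
#' correlations receive near-zero adjacency (a signed network).
#'
#' @param R correlation matrix in \[-1, 1\].
#' @param beta soft-threshold power (the published choices are 9 for
#'   promoter methylation and 8 for gene-body methylation networks).
#' @return adjacency matrix in \[0, 1\], zero diagonal.
#' @export
signedAdjacency <- function(R, beta) {
    stopifnot(beta >= 1, all(R >= -1 - 1e-8 & R <= 1 + 1e-8))
    A <- ((1 + R) / 2)^beta
    diag(A) <- 0
    A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu` and unit diagonal: similarity that rewards shared
#' network neighbourhoods on top of direct adjacency.
#'
#' @param A symmetric adjacency in \[0, 1\] with zero diagonal.
#' @return TOM matrix in \[0, 1\], unit diagonal.
#' @export
topologicalOverlap <- function(A) {
    stopifnot(all(abs(diag(A)) < 1e-12))
    k <- rowSums(A)
    num <- A %*% A + A
    den <- outer(k, k, pmin) + 1 - A
    tom <- num / den
    diag(tom) <- 1
    dimnames(tom) <- dimnames(A)
    tom
}

#' Bootstrap consensus topological overlap
#'
#' Resamples the samples with replacement `nBootstraps` times (one fixed
#' seed stream), builds a signed-bicor TOM on each bootstrap, and
#' combines them edge-wise by the median. Bootstraps in which a feature
#' becomes constant contribute `NA` at that feature's edges, which are
#' excluded from the median with a warning. With `nBootstraps = 1` and
#' `resample = FALSE` this is exactly the plain TOM.
#'
#' @param X numeric matrix, features x samples.
#' @param beta soft-threshold power.
#' @param nBootstraps number of bootstraps (the published analysis used
#'   100).
#' @param seed RNG seed for the bootstrap stream.
#' @param resample draw bootstrap samples (TRUE) or reuse the full
#'   sample set every time (FALSE).
#' @return consensus TOM matrix.
#' @export
consensusTOM <- function(X, beta, nBootstraps = 100, seed = 1,
                         resample = TRUE) {
    stopifnot(nBootstraps >= 1)
    set.seed(seed)
    p <- nrow(X); n <- ncol(X)
    toms <- array(NA_real_, c(p, p, nBootstraps))
    anyConstant <- FALSE
    for (b in seq_len(nBootstraps)) {
        idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
        Xb <- X[, idx, drop = FALSE]
        sds <- apply(Xb, 1, sd)
        if (any(sds == 0)) {
            anyConstant <- TRUE
            ok <- sds > 0
            tom <- matrix(NA_real_, p, p)
            sub <- topologicalOverlap(signedAdjacency(
                suppressMessages(bicorMatrix(Xb[ok, , drop = FALSE])), beta))
            tom[ok, ok] <- sub
            toms[, , b] <- tom
        } else {
            toms[, , b] <- topologicalOverlap(signedAdjacency(
                suppressMessages(bicorMatrix(Xb)), beta))
        }
    }
    if (anyConstant)
        warning("bootstrap(s) with constant features: undefined edges ",
                "excluded from the median")
    out <- apply(toms, c(1, 2), median, na.rm = TRUE)
    dimnames(out) <- list(rownames(X), rownames(X))
    out
}

#' Module eigengene
#'
#' First right-singular direction of the feature-standardized module
#' submatrix: a unit-norm per-sample summary profile. The sign is fixed
#' by the samples, not the features: the sample with the largest
#' absolute score is made positive. This makes the orientation invariant
#' to flipping the sign of every feature (the principal direction of a
#' module is defined only up to sign, so any feature-side anchor would
#' not be).
#'
#' @param X numeric matrix, features x samples.
#' @param features feature IDs of the module (>= 2, rows of `X`).
#' @return named numeric vector over samples.
#' @export
moduleEigengene <- function(X, features) {
    sub <- X[features, , drop = FALSE]
    stopifnot(nrow(sub) >= 2L)
    Z <- standardNormalize(sub)
    if (!nrow(Z)) stop("rank-0 module submatrix")
    sv <- svd(Z, nu = 0, nv = 1)
    if (sv$d[1] < 1e-12) stop("rank-0 module submatrix")
    eg <- sv$v[, 1]
    if (eg[which.max(abs(eg))] < 0) eg <- -eg
    names(eg) <- colnames(X)
    eg
}

#' Detect network modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a static
#' height chosen to maximize the weighted modularity of the resulting
#' partition over a grid of candidate heights (quantiles of the merge
#' heights); clusters smaller than `minModuleSize` become grey
#' (unassigned); modules whose eigengenes correlate above
#' `1 - mergeThreshold` are merged iteratively. This is a deliberately
#' simple, fully specified stand-in for dynamic branch-cutting: the
#' analysis surface downstream (eigengenes, trait associations,
#' enrichments, hubs) is unchanged.
#'
#' @param tom TOM matrix.
#' @param X the feature x sample data the TOM was built from (needed for
#'   eigengene-based merging and the kME table).
#' @param minModuleSize minimum module size (published value 100; scale
#'   down for small feature sets).
#' @param mergeThreshold eigengene-correlation merge threshold (0.1
#'   means modules correlated above 0.9 merge).
#' @param nHeights number of candidate cut heights.
#' @return a [ModuleSet-class]; labels are `M1`, `M2`, ... by decreasing
#'   size with `grey` for unassigned features.
#' @export
detectModules <- function(tom, X, minModuleSize = 100, mergeThreshold = 0.1,
                          nHeights = 25) {
    stopifnot(identical(rownames(tom), rownames(X)))
    d <- as.dist(1 - tom)
    hc <- hclust(d, method = "average")
    heights <- unique(quantile(hc$height,
                               probs = seq(0.05, 0.98, length.out = nHeights)))
    A <- (tom + t(tom)) / 2   # guard tiny asymmetry from the median step
    diag(A) <- 0
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    best <- NULL; bestQ <- -Inf
    for (h in heights) {
        cl <- cutree(hc, h = h)
        sizes <- table(cl)
        cl[cl %in% as.integer(names(sizes)[sizes < minModuleSize])] <- 0L
        if (!any(cl > 0L)) next
        # grey features count as singleton communities for modularity
        memb <- cl
        greyIdx <- which(memb == 0L)
        memb[greyIdx] <- max(cl) + seq_along(greyIdx)
        q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
        if (q > bestQ) { bestQ <- q; best <- cl }
    }
    feat <- rownames(tom)
    if (is.null(best)) {
        warning("no module of size >= ", minModuleSize, "; all grey")
        return(new("ModuleSet",
                   labels = setNames(rep("grey", length(feat)), feat),
                   eigengenes = matrix(numeric(0), ncol(X), 0,
                                       dimnames = list(colnames(X), NULL)),
                   kME = matrix(numeric(0), length(feat), 0,
                                dimnames = list(feat, NULL)),
                   params = list(minModuleSize = minModuleSize,
                                 mergeThreshold = mergeThreshold)))
    }
    labels <- best
    # iterative merge of near-identical eigengenes
    repeat {
        ids <- sort(unique(labels[labels > 0L]))
        if (length(ids) < 2L) break
        eg <- sapply(ids, function(m)
            moduleEigengene(X, feat[labels == m]))
        cc <- cor(eg)
        diag(cc) <- -Inf
        mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
        if (max(cc) <= 1 - mergeThreshold) break
        labels[labels == ids[mx[2]]] <- ids[mx[1]]
    }
    ids <- sort(unique(labels[labels > 0L]))
    ord <- ids[order(-vapply(ids, function(m) sum(labels == m), numeric(1)))]
    lab <- setNames(rep("grey", length(feat)), feat)
    for (i in seq_along(ord))
        lab[labels == ord[i]] <- paste0("M", i)
    mods <- paste0("M", seq_along(ord))
    eg <- sapply(mods, function(m) moduleEigengene(X, feat[lab == m]))
    eg <- matrix(eg, ncol = length(mods),
                 dimnames = list(colnames(X), mods))
    kme <- cor(t(X), eg)
    new("ModuleSet", labels = lab, eigengenes = eg, kME = kme,
        params = list(minModuleSize = minModuleSize,
                      mergeThreshold = mergeThreshold, modularity = bestQ))
}

#' Module eigengene-trait association
#'
#' Fits the differential mixed model of [differentialLMM()] with each
#' module eigengene as the response: eigengene ~ diagnosis + covariates
#' with a subject random intercept, Benjamini-Hochberg across modules.
#'
#' @param moduleSet a [ModuleSet-class] (or an eigengene matrix,
#'   samples x modules).
#' @param meta sample metadata.
#' @param design a [designSpec()].
#' @return `data.frame` with one row per module (`feature_id` is the
#'   module name).
#' @export
moduleTraitAssociation <- function(moduleSet, meta, design = designSpec()) {
    eg <- if (is(moduleSet, "ModuleSet")) moduleEigengenes(moduleSet)
          else moduleSet
    if (!ncol(eg)) stop("empty module set")
    Y <- t(eg)
    if (any(apply(Y, 1, sd) == 0)) stop("constant eigengene: degenerate fit")
    differentialLMM(Y, meta, design)
}

#' Module hubs by connectivity
#'
#' Members whose module membership (kME, correlation with the module
#' eigengene) reaches the module's empirical `1 - quantile` quantile;
#' ties are included. The published hub filter keeps the top 25% of a
#' module by kME.
#'
#' @param moduleSet a [ModuleSet-class].
#' @param module module name.
#' @param quantile top fraction to keep (default 0.25).
#' @return character vector of hub feature IDs.
#' @export
hubSelection <- function(moduleSet, module, quantile = 0.25) {
    lab <- moduleLabels(moduleSet)
    members <- names(lab)[lab == module]
    if (!length(members)) stop("module '", module, "' is empty")
    kme <- moduleKME(moduleSet)[members, module]
    th <- stats::quantile(kme, probs = 1 - quantile)
    members[kme >= th]
}

#' Gene-set over gene-set enrichment by logistic regression
#'
#' Per background gene, regresses membership of set 1 on membership of
#' set 2 with a logistic model; the enrichment odds ratio is the
#' exponentiated coefficient with its Wald p-value. If the fit separates
#' (e.g. identical or complementary sets), the Haldane-corrected (add
#' 1/2) odds ratio from the 2x2 table is reported with a Fisher exact
#' p-value, flagged in the `method` field.
#'
#' @param set1,set2 character vectors, subsets of `background`.
#' @param background character vector of the shared gene universe
#'   (>= 10 genes).
#' @return list with `oddsRatio`, `p`, `method` (`"logistic"` or
#'   `"haldane_fisher"`), `table`.
#' @export
genesetEnrichmentLogistic <- function(set1, set2, background) {
    if (!length(set1) || !length(set2)) stop("empty gene set")
    stopifnot(length(background) >= 10L,
              all(set1 %in% background), all(set2 %in% background))
    y <- as.integer(background %in% set1)
    x <- as.integer(background %in% set2)
    tab <- table(factor(y, 0:1), factor(x, 0:1))
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    pr <- fitted(fit)
    separated <- any(pr < 1e-8 | pr > 1 - 1e-8) ||
        any(abs(coef(fit)) > 15) || !fit$converged
    if (separated) {
        t2 <- tab + 0.5
        orr <- (t2[2, 2] * t2[1, 1]) / (t2[1, 2] * t2[2, 1])
        list(oddsRatio = unname(orr),
             p = fisher.test(tab)$p.value,
             method = "haldane_fisher", table = tab)
    } else {
        sm <- summary(fit)$coefficients
        list(oddsRatio = unname(exp(coef(fit)[2])), p = sm[2, 4],
             method = "logistic", table = tab)
    }
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p-value under the hypergeometric null by the probability-mass
#' rule: the sum of the probabilities of all tables (with the observed
#' margins) no more probable than the observed one. A zero margin gives
#' p = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
#' @examples
#' fisherExact2x2(matrix(c(11, 32, 1, 32), 2, 2, byrow = TRUE))
fisherExact2x2 <- function(tab) {
    tab <- as.matrix(tab)
    stopifnot(identical(dim(tab), c(2L, 2L)),
              all(tab >= 0), all(tab == round(tab)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    fisher.test(tab)$p.value
}
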