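#' @include AllClasses.R differential.R
#' @importFrom stats kmeans
#' @importFrom igraph graph_from_adjacency_matrix components modularity
NULL

#' Restrict a differential table to significant features
#'
#' Features with `q` below the layer's FDR threshold, in their original
#' (input) order. The published restriction thresholds are FDR < 10% for
#' mRNA, miRNA and promoter methylation and FDR < 20% for acetylation.
#'
#' @param diff a differential table from [differentialLMM()].
#' @param threshold FDR threshold in (0, 1].
#' @return character vector of feature IDs.
#' @export
selectDifferentialFeatures <- function(diff, threshold) {
    stopifnot(threshold > 0, threshold <= 1)
    if (threshold >= 1) return(diff$feature_id)
    sel <- diff$feature_id[!is.na(diff$q) & diff$q < threshold]
    if (!length(sel))
        stop("no feature passes q < ", threshold,
             "; similarity fusion is undefined on 0 features")
    sel
}

#' Feature-wise standard normalization
#'
#' Centers each feature (row) and scales it by its sample standard
#' deviation (n-1 denominator). Zero-variance features are dropped with a
#' warning.
#'
#' @param mat numeric matrix, features x samples.
#' @return normalized matrix.
#' @export
#' @examples
#' standardNormalize(matrix(c(1, 2, 3), 1, 3))
standardNormalize <- function(mat) {
    mu <- rowMeans(mat)
    sds <- apply(mat, 1, sd)
    if (any(sds == 0)) {
        warning("dropping ", sum(sds == 0), " zero-variance feature(s)")
        mat <- mat[sds > 0, , drop = FALSE]
        mu <- mu[sds > 0]; sds <- sds[sds > 0]
    }
    (mat - mu) / sds
}

#' Squared Euclidean sample-sample distances
#'
#' `D[i, j] = sum_f (x[f, i] - x[f, j])^2` over features; symmetric with
#' zero diagonal.
#'
#' @param mat numeric matrix, features x samples (no missing values).
#' @return n x n matrix over samples.
#' @export
squaredEuclidean <- function(mat) {
    stopifnot(!anyNA(mat))
    g <- crossprod(mat)                 # samples x samples
    sq <- diag(g)
    D <- outer(sq, sq, "+") - 2 * g
    D[D < 0] <- 0                       # numerical noise
    diag(D) <- 0
    dimnames(D) <- list(colnames(mat), colnames(mat))
    (D + t(D)) / 2
}

#' Scaled exponential affinity kernel
#'
#' The similarity kernel of the network-fusion method:
#' \deqn{W_{ij} = \exp\left(-\frac{\rho^2(x_i, x_j)}{\mu\,\epsilon_{ij}}\right),\quad
#'   \epsilon_{ij} = \frac{\bar\rho(x_i, N_i) + \bar\rho(x_j, N_j) + \rho(x_i, x_j)}{3}}
#' with \eqn{\rho} the Euclidean distance and \eqn{\bar\rho(x_i, N_i)}
#' the mean distance from sample i to its K nearest neighbours (self
#' excluded; rank ties broken by sample index). A floor of 1e-12 on
#' \eqn{\epsilon} guards duplicate samples. This is the published
#' exponential form of the kernel, not the Gaussian-density variant some
#' implementations substitute.
#'
#' @param D squared-distance matrix from [squaredEuclidean()].
#' @param params an [snfParams()]; `K` is capped at n-1 with a message.
#' @return symmetric affinity matrix with entries in (0, 1].
#' @export
snfAffinity <- function(D, params = snfParams()) {
    n <- nrow(D)
    K <- params@K
    if (K >= n) {
        message("K reduced to n-1 = ", n - 1)
        K <- n - 1L
    }
    rho <- sqrt(D)
    nnMean <- vapply(seq_len(n), function(i) {
        d <- rho[i, -i]
        mean(d[order(d)][seq_len(K)])   # stable order: ties by index
    }, numeric(1))
    eps <- (outer(nnMean, nnMean, "+") + rho) / 3
    eps <- pmax(eps, 1e-12)
    W <- exp(-D / (params@alpha * eps))
    dimnames(W) <- dimnames(D)
    (W + t(W)) / 2
}

# full-kernel transition matrix: off-diagonal mass 1/2, diagonal 1/2
.transitionFull <- function(W) {
    P <- W
    diag(P) <- 0
    rs <- rowSums(P)
    rs[rs == 0] <- 1
    P <- P / (2 * rs)
    diag(P) <- 0.5
    P
}

# K-NN local transition matrix: K largest off-diagonal entries per row
# (ties by index order), row-normalized; everything else zero
.transitionLocal <- function(W, K) {
    n <- nrow(W)
    S <- matrix(0, n, n, dimnames = dimnames(W))
    for (i in seq_len(n)) {
        w <- W[i, ]
        w[i] <- -Inf
        nn <- order(-w)[seq_len(K)]
        S[i, nn] <- W[i, nn] / sum(W[i, nn])
    }
    S
}

#' Similarity network fusion
#'
#' Cross-diffusion of per-layer affinity matrices into one fused
#' similarity network. Each layer v contributes a full-kernel transition
#' matrix \eqn{P^{(v)}} (off-diagonal mass 1/2, diagonal 1/2) and a
#' K-nearest-neighbour local transition matrix \eqn{S^{(v)}}
#' (row-normalized, self excluded). For `Tsteps` iterations each layer is
#' updated as
#' \deqn{P^{(v)} \leftarrow S^{(v)} \cdot \mathrm{mean}_{k \ne v} P^{(k)} \cdot S^{(v)\top},}
#' then symmetrized and re-normalized to the half/half row-stochastic
#' form (so every row sums to one at every iteration). The output is the
#' layer mean of the final transition matrices, symmetrized.
#'
#' @param affinities named list of affinity matrices over an identical
#'   sample set (same order).
#' @param params an [snfParams()].
#' @param trace if TRUE, returns the per-iteration transition matrices in
#'   an attribute (used by the validation suite).
#' @return fused n x n similarity matrix.
#' @export
snfFuse <- function(affinities, params = snfParams(), trace = FALSE) {
    m <- length(affinities)
    stopifnot(m >= 2L)
    ids <- lapply(affinities, colnames)
    for (v in seq_len(m)[-1]) {
        if (!identical(ids[[1]], ids[[v]])) {
            dif <- c(setdiff(ids[[1]], ids[[v]]), setdiff(ids[[v]], ids[[1]]))
            stop("sample sets differ across layers; symmetric difference: ",
                 paste(unique(dif), collapse = ", "))
        }
    }
    n <- nrow(affinities[[1]])
    K <- min(params@K, n - 1L)
    P <- lapply(affinities, .transitionFull)
    S <- lapply(affinities, function(W) .transitionLocal(W, K))
    hist <- if (trace) list(P) else NULL
    for (t in seq_len(params@Tsteps)) {
        newP <- vector("list", m)
        for (v in seq_len(m)) {
            other <- Reduce(`+`, P[-v]) / (m - 1)
            Pv <- S[[v]] %*% other %*% t(S[[v]])
            Pv <- (Pv + t(Pv)) / 2
            newP[[v]] <- .transitionFull(Pv)
        }
        P <- newP
        if (trace) hist[[t + 1L]] <- P
    }
    fused <- Reduce(`+`, P) / m
    fused <- (fused + t(fused)) / 2
    dimnames(fused) <- dimnames(affinities[[1]])
    if (trace) attr(fused, "history") <- hist
    fused
}

#' Normalized-cut spectral clustering of a similarity matrix
#'
#' Embeds the samples with the top-k eigenvectors of the symmetric
#' normalized Laplacian, row-normalizes the embedding, and partitions it
#' with k-means (fixed seed, `nstart` restarts, best within-cluster sum
#' of squares). With `orientScores` supplied, cluster labels are assigned
#' in increasing order of the clusters' mean score, so label k is the
#' cluster loading highest on the differential signature (the convergent
#' candidate for k = 2).
#'
#' @param W symmetric nonnegative similarity matrix.
#' @param k number of clusters.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of k-means restarts (default 50).
#' @param orientScores optional numeric vector aligned to the samples
#'   (higher = stronger differential-signature loading).
#' @return named integer vector of labels in 1..k.
#' @export
spectralCluster <- function(W, k = 2, seed = 1, nstart = 50,
                            orientScores = NULL) {
    stopifnot(isSymmetric(unname(W), tol = 1e-8), all(W >= 0))
    g <- graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                     diag = FALSE)
    ncomp <- components(g)$no
    if (ncomp > k)
        stop("similarity graph has ", ncomp, " components > k = ", k)
    d <- rowSums(W)
    d[d == 0] <- 1
    Dhalf <- 1 / sqrt(d)
    Lsym <- diag(nrow(W)) - (Dhalf * W) %*% diag(Dhalf)
    ev <- eigen(Lsym, symmetric = TRUE)
    U <- ev$vectors[, rev(seq(ncol(Lsym) - k + 1, ncol(Lsym))), drop = FALSE]
    rn <- sqrt(rowSums(U^2))
    rn[rn == 0] <- 1
    U <- U / rn
    set.seed(seed)
    km <- kmeans(U, centers = k, nstart = nstart, iter.max = 100)
    labels <- km$cluster
    if (!is.null(orientScores)) {
        meanScore <- vapply(seq_len(k), function(cl)
            mean(orientScores[labels == cl]), numeric(1))
        relabel <- match(seq_len(k), order(meanScore))
        labels <- relabel[labels]
    }
    names(labels) <- colnames(W)
    labels
}

#' Signed differential-signature score per sample
#'
#' Mean over layers of the sign-weighted average of each layer's
#' standardized differential features: positive for samples loading in
#' the disease direction of the planted/estimated signature. Used to
#' orient cluster labels and principal-component signs.
#'
#' @param normLayers named list of standardized feature x sample matrices
#'   (already restricted to the differential features).
#' @param diffTables named list of differential tables aligned to the
#'   layers.
#' @return named numeric vector over the common samples.
#' @export
signatureScores <- function(normLayers, diffTables) {
    scores <- lapply(names(normLayers), function(l) {
        m <- normLayers[[l]]
        d <- diffTables[[l]]
        sg <- sign(d$estimate)[match(rownames(m), d$feature_id)]
        colMeans(m * sg)
    })
    Reduce(`+`, scores) / length(scores)
}

#' Full SNF subtyping pipeline
#'
#' Runs the discovery stage on the samples observed in all layers:
#' covariate adjustment preserving diagnosis, an initial all-cases vs
#' control differential pass per layer, restriction to differential
#' features at per-layer FDR thresholds, feature standardization,
#' squared-distance and affinity computation, similarity network fusion,
#' and spectral bipartition. Cluster label 2 is the group loading highest
#' on the differential signature — the convergent-subtype candidate.
#'
#' @param cohort a [MultiOmicCohort-class].
#' @param params an [snfParams()].
#' @param thresholds named per-layer FDR restriction thresholds
#'   (defaults: mRNA 0.1, miRNA 0.1, meth 0.1, acetyl 0.2).
#' @param design a [designSpec()] shared by all layers, or a named list
#'   of per-layer designs (default [layerDesigns()]).
#' @param seed seed for the spectral k-means restarts.
#' @param layers which layers to use (default: all in the cohort).
#' @return list with elements `labels` (named integer, 1/2), `fused`,
#'   `affinities`, `normLayers`, `diffTables`, `selected`, `scores`,
#'   `samples`.
#' @export
snfSubtype <- function(cohort, params = snfParams(),
                       thresholds = c(mRNA = 0.1, miRNA = 0.1,
                                      meth = 0.1, acetyl = 0.2),
                       design = layerDesigns(), seed = 1,
                       layers = layerNames(cohort)) {
    meta <- as.data.frame(sampleData(cohort))
    common <- Reduce(intersect, lapply(layers, function(l)
        colnames(omicLayer(cohort, l))))
    if (length(common) < 4L) stop("fewer than 4 samples in all layers")
    metaC <- meta[meta$sample_id %in% common, , drop = FALSE]

    normLayers <- list(); diffTables <- list(); selected <- list()
    affinities <- list()
    for (l in layers) {
        des <- if (inherits(design, "DesignSpec")) design else design[[l]]
        m <- omicLayer(cohort, l)[, common, drop = FALSE]
        adj <- regressOutCovariates(m, metaC, des)
        diff <- differentialLMM(adj, metaC, des)
        sel <- selectDifferentialFeatures(diff, thresholds[[l]])
        nm <- standardNormalize(adj[sel, , drop = FALSE])
        normLayers[[l]] <- nm
        diffTables[[l]] <- diff
        selected[[l]] <- sel
        affinities[[l]] <- snfAffinity(squaredEuclidean(nm), params)
    }
    fused <- snfFuse(affinities, params)
    scores <- signatureScores(normLayers, diffTables)
    labels <- spectralCluster(fused, k = params@kClusters, seed = seed,
                              orientScores = scores)
    list(labels = labels, fused = fused, affinities = affinities,
         normLayers = normLayers, diffTables = diffTables,
         selected = selected, scores = scores, samples = common)
}

#' Leave-one-dataset-out clustering stability
#'
#' Re-runs the subtyping pipeline leaving out each layer in turn and
#' reports, for each leave-out, the fraction of samples assigned to the
#' same group as the full four-layer clustering (after optimal two-label
#' matching).
#'
#' @param cohort a [MultiOmicCohort-class] with >= 3 layers.
#' @param params,thresholds,design,seed as in [snfSubtype()].
#' @return list with `full` (the full-data result), `leaveOut` (per-layer
#'   results) and `concordance` (named numeric vector).
#' @export
leaveOneDatasetOut <- function(cohort, params = snfParams(),
                               thresholds = c(mRNA = 0.1, miRNA = 0.1,
                                              meth = 0.1, acetyl = 0.2),
                               design = layerDesigns(), seed = 1) {
    lay <- layerNames(cohort)
    stopifnot(length(lay) >= 3L)
    full <- snfSubtype(cohort, params, thresholds, design, seed)
    res <- list(); conc <- numeric(0)
    for (l in lay) {
        sub <- snfSubtype(cohort, params, thresholds, design, seed,
                          layers = setdiff(lay, l))
        res[[l]] <- sub
        conc[[l]] <- assignmentConcordance(full$labels, sub$labels)
    }
    list(full = full, leaveOut = res, concordance = conc)
}
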