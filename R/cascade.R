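#' @include AllClasses.R snf.R
#' @importFrom stats glm binomial plogis coef predict
NULL

#' PC1 sample loadings as standardized predictor scores
#'
#' Computes each sample's loading on the first principal component of a
#' layer's (feature-centered) differential-feature matrix, orients the
#' sign so that the mean loading of the reference group-2 (convergent)
#' training samples is positive, and standardizes to Z-scores. The
#' standardization moments are taken over all scored samples
#' (`standardize = "union"`, the default) or over the training samples
#' only (`"training"`).
#'
#' @param mat numeric matrix, differential features x samples (covariate-
#'   adjusted), >= 2 features and >= 2 samples.
#' @param referenceLabels named integer vector (1/2) of SNF group labels
#'   for the training samples.
#' @param standardize `"union"` or `"training"`.
#' @return named numeric vector of Z-scores over `colnames(mat)`.
#' @export
pc1Zscores <- function(mat, referenceLabels,
                       standardize = c("union", "training")) {
    standardize <- match.arg(standardize)
    stopifnot(nrow(mat) >= 1L, ncol(mat) >= 2L)
    centered <- mat - rowMeans(mat)
    sv <- svd(centered, nu = 0, nv = 1)
    if (sv$d[1] < 1e-12) stop("degenerate (rank-0) matrix")
    scores <- sv$v[, 1] * sv$d[1]
    names(scores) <- colnames(mat)
    train2 <- names(referenceLabels)[referenceLabels == 2L]
    train2 <- intersect(train2, names(scores))
    if (!length(train2)) stop("no reference group-2 sample among columns")
    if (mean(scores[train2]) < 0) scores <- -scores
    ref <- if (standardize == "union") scores
           else scores[intersect(names(referenceLabels), names(scores))]
    (scores - mean(ref)) / sd(ref)
}

#' Enumerate classifier availability patterns
#'
#' All subsets of the four layers with 1 to 3 members, minus the patterns
#' absent from the study cohort (no sample was observed in
#' miRNA/methylation/acetylation only, nor in miRNA only), yielding
#' twelve patterns: 3 triples, 6 pairs, 3 singles.
#'
#' @param layers layer names (default [omicLayerNames()]).
#' @param exclude list of character vectors, patterns to drop.
#' @return list of character vectors (sorted canonical order).
#' @export
cascadePatterns <- function(layers = omicLayerNames(),
                            exclude = list(c("miRNA", "meth", "acetyl"),
                                           "miRNA")) {
    pats <- list()
    for (k in seq_len(length(layers) - 1L))
        pats <- c(pats, utils::combn(layers, k, simplify = FALSE))
    excl <- vapply(exclude, patternKey, character(1))
    keep <- vapply(pats, function(p) !(patternKey(p) %in% excl), logical(1))
    pats[keep]
}

#' Canonical key of an availability pattern
#'
#' Locale-independent (C-order) sorted layer names joined by `+`; the
#' registry key under which [trainCascade()] stores each model.
#'
#' @param pattern character vector of layer names.
#' @return single string.
#' @export
patternKey <- function(pattern) {
    paste(sort(pattern, method = "radix"), collapse = "+")
}

#' Firth-penalized logistic regression
#'
#' Newton iteration on the Jeffreys-penalized likelihood (score adjusted
#' by the hat leverages), which yields finite estimates under complete
#' separation. Used as the fallback when the unpenalized fit separates.
#'
#' @param X design matrix including the intercept column.
#' @param y 0/1 response.
#' @param maxit,tol iteration controls.
#' @return named coefficient vector.
#' @export
firthLogistic <- function(X, y, maxit = 100, tol = 1e-8) {
    b <- rep(0, ncol(X))
    for (it in seq_len(maxit)) {
        eta <- drop(X %*% b)
        p <- plogis(eta)
        w <- pmax(p * (1 - p), 1e-10)
        XW <- X * sqrt(w)
        XtWX <- crossprod(XW)
        h <- rowSums((XW %*% solve(XtWX)) * XW)
        U <- crossprod(X, y - p + h * (0.5 - p))
        step <- solve(XtWX, U)
        b <- b + drop(step)
        if (max(abs(U)) < tol) break
    }
    names(b) <- colnames(X)
    b
}

.fitLogistic <- function(X, y) {
    df <- data.frame(y = y, X)
    sepWarn <- FALSE
    fit <- withCallingHandlers(
        glm(y ~ ., data = df, family = binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                sepWarn <<- TRUE
            invokeRestart("muffleWarning")
        })
    pr <- fitted(fit)
    separated <- sepWarn || any(pr < 1e-8 | pr > 1 - 1e-8) ||
        any(abs(coef(fit)) > 15)
    if (separated) {
        Xd <- cbind(`(Intercept)` = 1, as.matrix(X))
        list(coef = firthLogistic(Xd, y), firth = TRUE)
    } else {
        list(coef = coef(fit), firth = FALSE)
    }
}

.predictLogistic <- function(coefs, X) {
    Xd <- cbind(1, as.matrix(X))
    drop(plogis(Xd %*% coefs))
}

#' Train the availability-pattern classifier cascade
#'
#' For each availability pattern, fits a logistic regression of the SNF
#' group label (0 = group 1, 1 = group 2) on the pattern's per-layer PC1
#' Z-scores over the training samples (the SNF-clustered set, which has
#' all four layers). Leave-one-out predicted probabilities are computed
#' by refitting n times; the decision cutoff is the accuracy-maximizing
#' value over the midpoints between sorted LOO probabilities (plus the
#' extremes), ties resolved toward 0.5. Fits that separate fall back to
#' Firth-penalized estimates and are flagged.
#'
#' @param scores numeric matrix, samples x layers, of [pc1Zscores()]
#'   values (NA where a sample lacks the layer).
#' @param labels named integer vector (1/2) of SNF group labels for the
#'   training samples.
#' @param patterns list of availability patterns (default
#'   [cascadePatterns()]).
#' @param includeFull also train a model on all four layers (not part of
#'   the twelve-pattern cascade; used for training-set validation).
#' @return list of models, each with `pattern`, `coef`, `firth`,
#'   `cutoff`, `looAccuracy`, `looProbs`.
#' @export
trainCascade <- function(scores, labels,
                         patterns = cascadePatterns(colnames(scores)),
                         includeFull = FALSE) {
    train <- intersect(names(labels),
                       rownames(scores)[rowSums(is.na(scores)) == 0])
    if (length(train) < 6L) stop("too few complete training samples")
    y <- as.integer(labels[train] == 2L)
    if (includeFull) patterns <- c(patterns, list(colnames(scores)))
    models <- lapply(patterns, function(pat) {
        X <- scores[train, pat, drop = FALSE]
        fit <- .fitLogistic(X, y)
        loo <- vapply(seq_along(train), function(i) {
            f <- .fitLogistic(X[-i, , drop = FALSE], y[-i])
            .predictLogistic(f$coef, X[i, , drop = FALSE])
        }, numeric(1))
        cand <- sort(unique(loo))
        cuts <- unique(c(0, (cand[-1] + cand[-length(cand)]) / 2, 1))
        acc <- vapply(cuts, function(ct)
            mean((loo >= ct) == (y == 1L)), numeric(1))
        best <- which(acc == max(acc))
        cutoff <- cuts[best][which.min(abs(cuts[best] - 0.5))]
        list(pattern = sort(pat, method = "radix"), coef = fit$coef,
             firth = fit$firth, cutoff = cutoff, looAccuracy = max(acc),
             looProbs = loo)
    })
    names(models) <- vapply(models, function(m) patternKey(m$pattern),
                            character(1))
    models
}

#' Classify samples through the cascade
#'
#' Each sample is routed to the model whose availability pattern equals
#' the set of layers in which the sample is observed; its predicted
#' probability is compared with that model's cutoff (probability at or
#' above the cutoff means group 2 — the convergent candidate). An
#' availability pattern without a trained model is an error naming the
#' pattern.
#'
#' @param scores numeric matrix, samples x layers, with NA marking
#'   unobserved layers.
#' @param models output of [trainCascade()].
#' @param diagnosis optional named character vector (`ASD`/`Control`);
#'   when given, ASD samples in group 2 are called `convergent`, ASD in
#'   group 1 `disparate`, controls `control`.
#' @param skipUnsupported drop samples whose availability pattern has no
#'   trained model, with a message (default FALSE: such a sample is an
#'   error naming the pattern).
#' @return `data.frame` with `sample_id`, `pattern`, `prob`, `group` and
#'   (if diagnosis given) `subtype_call`.
#' @export
classifySamples <- function(scores, models, diagnosis = NULL,
                            skipUnsupported = FALSE) {
    out <- lapply(rownames(scores), function(s) {
        pat <- colnames(scores)[!is.na(scores[s, ])]
        if (!length(pat)) {
            if (skipUnsupported) {
                message("skipping ", s, " (observed in no layer)")
                return(NULL)
            }
            stop("sample ", s, " observed in no layer")
        }
        key <- patternKey(pat)
        if (!key %in% names(models)) {
            if (skipUnsupported) {
                message("skipping ", s, " (untrained pattern ", key, ")")
                return(NULL)
            }
            stop("no trained model for availability pattern: ", key)
        }
        m <- models[[key]]
        prob <- .predictLogistic(m$coef, scores[s, m$pattern, drop = FALSE])
        data.frame(sample_id = s, pattern = key, prob = prob,
                   group = ifelse(prob >= m$cutoff, 2L, 1L),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    if (!is.null(diagnosis)) {
        dg <- diagnosis[res$sample_id]
        res$subtype_call <- ifelse(dg == "Control", "control",
                                   ifelse(res$group == 2L, "convergent",
                                          "disparate"))
    }
    res
}

#' Fraction of identically assigned samples after label matching
#'
#' Agreement between two labelings of the same samples, maximized over
#' the permutations of the second labeling's labels (so wholesale label
#' swaps count as perfect agreement).
#'
#' @param a,b named label vectors over a shared sample set.
#' @return fraction in \[0, 1\].
#' @export
assignmentConcordance <- function(a, b) {
    shared <- intersect(names(a), names(b))
    if (!length(shared)) stop("disjoint sample sets")
    a <- as.character(a[shared]); b <- as.character(b[shared])
    ub <- unique(b)
    perms <- .permutations(ub)
    best <- 0
    for (p in perms) {
        m <- setNames(p, ub)
        best <- max(best, mean(a == m[b]))
    }
    best
}

.permutations <- function(x) {
    if (length(x) <= 1L) return(list(x))
    out <- list()
    for (i in seq_along(x))
        for (rest in .permutations(x[-i]))
            out[[length(out) + 1L]] <- c(x[i], rest)
    out
}

#' Layer scores for a whole cohort, anchored on an SNF result
#'
#' For every layer: adjusts the full layer matrix (all samples observed
#' in that layer) for nuisance covariates, restricts it to the features
#' the SNF stage selected, and computes oriented PC1 Z-scores anchored on
#' the SNF training labels.
#'
#' @param cohort a [MultiOmicCohort-class].
#' @param snfResult result of [snfSubtype()].
#' @param design a [designSpec()] or per-layer list ([layerDesigns()]).
#' @param standardize passed to [pc1Zscores()].
#' @return numeric matrix, samples x layers, NA where unobserved.
#' @export
cascadeScores <- function(cohort, snfResult, design = layerDesigns(),
                          standardize = "union") {
    meta <- as.data.frame(sampleData(cohort))
    lay <- names(snfResult$normLayers)
    scores <- matrix(NA_real_, nrow(meta), length(lay),
                     dimnames = list(meta$sample_id, lay))
    for (l in lay) {
        des <- if (inherits(design, "DesignSpec")) design else design[[l]]
        m <- omicLayer(cohort, l)
        adj <- regressOutCovariates(m, meta[meta$sample_id %in% colnames(m), ,
                                            drop = FALSE], des)
        sel <- intersect(snfResult$selected[[l]], rownames(adj))
        z <- pc1Zscores(adj[sel, , drop = FALSE], snfResult$labels,
                        standardize = standardize)
        scores[names(z), l] <- z
    }
    scores
}

#' Region discordance of subtype assignments
#'
#' For subjects contributing both frontal and temporal samples, tabulates
#' whether the two samples were assigned to different groups, split by
#' diagnosis, and tests the 2x2 table with Fisher's exact test.
#'
#' @param groups named vector sample -> group label (1/2 or subtype call).
#' @param meta sample metadata with `sample_id`, `subject_id`,
#'   `diagnosis`, `region`.
#' @return list with `table` (2x2: diagnosis x discordant/concordant) and
#'   `p` (two-sided Fisher).
#' @export
regionDiscordance <- function(groups, meta) {
    meta <- as.data.frame(meta)
    meta <- meta[meta$sample_id %in% names(groups), ]
    split_ <- split(meta, meta$subject_id)
    rows <- lapply(split_, function(d) {
        if (length(unique(d$region)) < 2L) return(NULL)
        data.frame(diagnosis = d$diagnosis[1],
                   discordant = length(unique(groups[d$sample_id])) > 1L)
    })
    df <- do.call(rbind, rows)
    if (is.null(df) || !nrow(df)) stop("no paired-region subjects")
    tab <- matrix(c(sum(df$diagnosis == "ASD" & df$discordant),
                    sum(df$diagnosis == "ASD" & !df$discordant),
                    sum(df$diagnosis != "ASD" & df$discordant),
                    sum(df$diagnosis != "ASD" & !df$discordant)),
                  2, 2, byrow = TRUE,
                  dimnames = list(c("ASD", "Control"),
                                  c("discordant", "concordant")))
    list(table = tab, p = fisherExact2x2(tab))
}
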