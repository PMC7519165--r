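#' @include AllClasses.R
#' @importFrom stats model.matrix pt p.adjust cor sd terms as.formula lm
#' @importFrom lme4 lmer refit fixef isSingular lmerControl
NULL

#' Per-layer default differential designs
#'
#' Each omics layer is modelled with its own covariate set, mirroring how
#' the assays differ: RNA measures carry RNA-quality and sequencing
#' covariates (RIN, sequencing PC, PMI), methylation and acetylation
#' carry array batch and cell-composition (CET) covariates. All models
#' share diagnosis, age, sex, region and brain bank, and use the subject
#' ID as the random-intercept group.
#'
#' @return named list of [designSpec()] objects over [omicLayerNames()].
#' @export
#' @examples
#' names(layerDesigns())
layerDesigns <- function() {
    list(
        mRNA = designSpec(fixed = c("diagnosis", "age", "sex", "region",
                                    "RIN", "bank", "batch", "seqPC1")),
        miRNA = designSpec(fixed = c("diagnosis", "age", "sex", "region",
                                     "RIN", "bank", "PMI")),
        meth = designSpec(fixed = c("diagnosis", "age", "sex", "region",
                                    "bank", "batch", "CET")),
        acetyl = designSpec(fixed = c("diagnosis", "age", "sex", "region",
                                      "bank", "CET")))
}

#' Specify a differential design
#'
#' Describes the fixed-effect structure of the per-feature models: the
#' tested variable (first element of `keep`, e.g. `diagnosis`), the
#' nuisance covariates, the effects that must survive covariate removal,
#' and the grouping variable for the subject-level random intercept.
#'
#' @param fixed character vector of metadata columns entering the fixed
#'   effects; the first element of `keep` is the tested variable.
#' @param keep effects not regressed out by [regressOutCovariates()]
#'   (subset of `fixed`).
#' @param group metadata column of the random-intercept grouping (the
#'   subject/brain ID).
#' @return A `DesignSpec` (list with class attribute).
#' @export
#' @examples
#' designSpec()
designSpec <- function(fixed = c("diagnosis", "age", "sex", "region",
                                 "bank", "batch", "RIN", "CET"),
                       keep = "diagnosis",
                       group = "subject_id") {
    if (!all(keep %in% fixed))
        stop("keep effects must be a subset of the fixed covariates")
    structure(list(fixed = fixed, keep = keep, group = group),
              class = "DesignSpec")
}

# fixed-effect model matrix for a design on a metadata subset; constant
# covariates are dropped (single level after subsetting), genuine
# aliasing raises an error naming the aliased columns
.designMatrix <- function(meta, design) {
    meta <- as.data.frame(meta)
    vars <- design$fixed
    usable <- vars[vapply(vars, function(v) {
        x <- meta[[v]]
        if (is.null(x)) stop("metadata lacks design column '", v, "'")
        length(unique(x)) > 1L
    }, logical(1))]
    if (!all(design$keep %in% usable))
        stop("tested effect '", paste(design$keep, collapse = ","),
             "' is constant in this sample subset")
    # categorical terms: treatment coding, first alphabetical level as
    # reference (control precedes the subtype labels alphabetically only
    # by accident, so diagnosis/subtype columns should be factors with
    # the control level first; character columns are sorted)
    for (v in usable) if (is.character(meta[[v]]))
        meta[[v]] <- factor(meta[[v]])
    X <- model.matrix(as.formula(paste("~", paste(usable, collapse = "+"))),
                      meta)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stop("rank-deficient design; aliased columns: ",
             paste(aliased, collapse = ", "))
    }
    keepCols <- which(attr(X, "assign") %in%
                      match(design$keep, usable))
    list(X = X, qr = qrX, keepCols = keepCols, vars = usable)
}

# vectorized OLS over all features: one QR, per-feature sigma
.olsAllFeatures <- function(Y, X, qrX, testCol) {
    n <- ncol(Y); p <- ncol(X)
    B <- qr.coef(qrX, t(Y))                       # p x features
    res <- t(Y) - X %*% B
    rss <- colSums(res^2)
    df <- n - p
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(XtXinv[testCol, testCol] * rss / df)
    est <- B[testCol, ]
    tval <- est / se
    pval <- 2 * pt(-abs(tval), df)
    data.frame(estimate = est, se = se, p = pval)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment. Missing p-values propagate as
#' `NA` and are excluded from the number of tests.
#'
#' @param p numeric vector of p-values in \[0,1\] (NA allowed).
#' @return numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
bhFDR <- function(p) {
    q <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0,1]")
    q[ok] <- p.adjust(p[ok], method = "BH")
    q
}

#' Per-feature differential statistics with a subject random intercept
#'
#' Fits, for every feature (row), a linear mixed model of the feature on
#' the design's fixed effects with a random intercept on the grouping
#' variable (the subject/brain ID), by REML. The reported statistic is
#' the Wald t of the tested coefficient with residual degrees of freedom
#' `n - p`, and q-values are Benjamini-Hochberg across the features of
#' the call. When every subject contributes a single sample the random
#' intercept is unidentifiable and the fit reduces to ordinary least
#' squares (computed in one pass for all features); features whose mixed
#' fit is singular likewise fall back to OLS and are flagged in the
#' `method` column.
#'
#' The tested variable is the first `keep` effect of the design; its
#' reported coefficient is the effect of the second factor level versus
#' the first (treatment coding).
#'
#' @param mat numeric matrix, features x samples.
#' @param meta per-sample metadata (`data.frame` or `DataFrame`) aligned
#'   to `colnames(mat)` via its `sample_id` column.
#' @param design a [designSpec()].
#' @return `data.frame` with columns `feature_id`, `estimate`, `se`, `p`,
#'   `q`, `direction` (`"+"`/`"-"`), `method` (`"lmm"`/`"ols"`).
#' @export
differentialLMM <- function(mat, meta, design = designSpec()) {
    meta <- as.data.frame(meta)
    stopifnot(!is.null(colnames(mat)), "sample_id" %in% names(meta))
    meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
    testVar <- design$keep[1]
    lv <- sort(unique(as.character(meta[[testVar]])))
    if (length(lv) != 2L)
        stop("tested variable '", testVar, "' must have exactly 2 levels")
    # reference level: control if present, else first alphabetical, so the
    # reported coefficient is the case-group effect
    ctrlLike <- lv[tolower(lv) %in% c("control", "ctl", "ctrl")]
    if (length(ctrlLike) == 1L) lv <- c(ctrlLike, setdiff(lv, ctrlLike))
    meta[[testVar]] <- factor(as.character(meta[[testVar]]), levels = lv)
    if (min(table(meta[[testVar]])) < 2L)
        stop("need >= 2 samples per group of '", testVar, "'")
    dm <- .designMatrix(meta, design)
    testCol <- dm$keepCols[1]

    groups <- meta[[design$group]]
    singletons <- all(table(groups) == 1L)
    if (singletons) {
        res <- .olsAllFeatures(mat, dm$X, dm$qr, testCol)
        res$method <- "ols"
    } else {
        dat <- data.frame(dm$X[, -1, drop = FALSE], check.names = FALSE)
        names(dat) <- paste0("x", seq_len(ncol(dat)))
        dat$.g <- factor(groups)
        form <- as.formula(paste("y ~", paste(names(dat)[seq_len(ncol(dat) - 1)],
                                              collapse = "+"), "+ (1 | .g)"))
        dat$y <- mat[1, ]
        ctrl <- lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
        base <- suppressMessages(lmer(form, data = dat, REML = TRUE,
                                      control = ctrl))
        olsFallback <- .olsAllFeatures(mat, dm$X, dm$qr, testCol)
        nFeat <- nrow(mat)
        est <- se <- pv <- numeric(nFeat)
        method <- character(nFeat)
        df <- ncol(mat) - ncol(dm$X)
        for (i in seq_len(nFeat)) {
            fit <- tryCatch(suppressMessages(refit(base, mat[i, ])),
                            error = function(e) NULL)
            if (is.null(fit) || isSingular(fit, tol = 1e-5)) {
                est[i] <- olsFallback$estimate[i]
                se[i] <- olsFallback$se[i]
                pv[i] <- olsFallback$p[i]
                method[i] <- "ols"
            } else {
                b <- fixef(fit)[testCol]
                s <- sqrt(as.matrix(vcov(fit))[testCol, testCol])
                est[i] <- b; se[i] <- s
                pv[i] <- 2 * pt(-abs(b / s), df)
                method[i] <- "lmm"
            }
        }
        res <- data.frame(estimate = est, se = se, p = pv, method = method)
    }
    data.frame(feature_id = rownames(mat),
               estimate = res$estimate, se = res$se, p = res$p,
               q = bhFDR(res$p),
               direction = ifelse(res$estimate >= 0, "+", "-"),
               method = res$method,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Subtype-versus-control differential contrast
#'
#' Subsets a layer to the samples of one ASD subtype plus all controls
#' (per a sample-level subtype labelling) and runs [differentialLMM()].
#'
#' @param mat numeric matrix, features x samples.
#' @param meta per-sample metadata with `sample_id` and `diagnosis`.
#' @param labels named character vector sample -> subtype
#'   (`convergent` / `disparate` / `control`).
#' @param subtype which ASD subtype to contrast against controls.
#' @param design a [designSpec()]; the tested variable is `diagnosis`.
#' @return A differential table as in [differentialLMM()].
#' @export
subtypeDifferential <- function(mat, meta, labels, subtype,
                                design = designSpec()) {
    meta <- as.data.frame(meta)
    lab <- labels[meta$sample_id]
    keep <- meta$sample_id[lab %in% c(subtype, "control") &
                           meta$sample_id %in% colnames(mat)]
    if (length(keep) < 4L) stop("too few samples in contrast")
    differentialLMM(mat[, keep, drop = FALSE],
                    meta[meta$sample_id %in% keep, , drop = FALSE], design)
}

#' Remove low-connectivity outlier samples
#'
#' Computes each sample's mean correlation to all other samples,
#' standardizes these means to Z-scores, and removes samples on the
#' low-connectivity side (`Z < -zThresh`); the screen is then applied
#' once more to the reduced set. Constant (zero-variance) samples are
#' removed up front with a warning.
#'
#' @param mat numeric matrix, features x samples (>= 4 samples).
#' @param zThresh removal threshold on the standardized mean correlation
#'   (default 3).
#' @return character vector of kept sample IDs.
#' @export
removeOutlierSamples <- function(mat, zThresh = 3) {
    stopifnot(ncol(mat) >= 4L)
    keep <- colnames(mat)
    sds <- apply(mat, 2, sd)
    if (any(sds == 0)) {
        warning("removing constant sample(s): ",
                paste(keep[sds == 0], collapse = ", "))
        keep <- keep[sds > 0]
    }
    for (pass in 1:2) {
        if (length(keep) < 4L) break
        cc <- cor(mat[, keep, drop = FALSE])
        meanCor <- (rowSums(cc) - 1) / (length(keep) - 1)
        z <- (meanCor - mean(meanCor)) / sd(meanCor)
        drop <- which(z < -zThresh)
        if (!length(drop)) break
        keep <- keep[-drop]
    }
    keep
}

#' Regress nuisance covariates out of a matrix
#'
#' Fits the full fixed-effect design to every feature and returns the
#' matrix with the fitted contribution of the nuisance covariates
#' removed: intercept + kept effects (e.g. diagnosis) + residuals. The
#' variance associated with the kept effects is preserved exactly.
#'
#' @param mat numeric matrix, features x samples.
#' @param meta per-sample metadata with `sample_id`.
#' @param design a [designSpec()]; `design$keep` lists the preserved
#'   effects.
#' @return adjusted matrix, same dimensions and dimnames.
#' @export
regressOutCovariates <- function(mat, meta, design = designSpec()) {
    meta <- as.data.frame(meta)
    meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
    dm <- .designMatrix(meta, design)
    B <- qr.coef(dm$qr, t(mat))                    # p x features
    nuis <- setdiff(seq_len(ncol(dm$X)), c(1L, dm$keepCols))
    if (!length(nuis)) return(mat)
    adj <- mat - t(dm$X[, nuis, drop = FALSE] %*% B[nuis, , drop = FALSE])
    dimnames(adj) <- dimnames(mat)
    adj
}

#' ChIP-seq sample QC filter
#'
#' Keeps a sample iff it violates none of the six published thresholds:
#' total reads < 10,000,000; aligned read fraction < 75%; duplicate read
#' fraction > 30%; normalized strand coefficient (NSC) < 1.03; relative
#' strand correlation (RSC) < 0.5; fraction of reads in peaks (FRiP)
#' < 11%. Violations are strict inequalities, so a sample exactly at a
#' threshold is kept. A missing metric removes the sample with a warning.
#'
#' @param metrics `data.frame` with columns `sample_id`, `total_reads`,
#'   `align_frac`, `dup_frac`, `nsc`, `rsc`, `frip`.
#' @return character vector of kept sample IDs.
#' @export
chipseqQCFilter <- function(metrics) {
    need <- c("total_reads", "align_frac", "dup_frac", "nsc", "rsc", "frip")
    if (!all(need %in% names(metrics)))
        stop("metrics table lacks columns: ",
             paste(setdiff(need, names(metrics)), collapse = ", "))
    fails <- with(metrics,
        total_reads < 1e7 | align_frac < 0.75 | dup_frac > 0.30 |
        nsc < 1.03 | rsc < 0.5 | frip < 0.11)
    hasNA <- rowSums(is.na(metrics[need])) > 0
    if (any(hasNA)) {
        warning("samples with missing QC metrics removed: ",
                paste(metrics$sample_id[hasNA], collapse = ", "))
        fails[hasNA] <- TRUE
    }
    metrics$sample_id[!fails]
}

#' One-versus-rest cluster marker detection
#'
#' For each cluster, fits a per-gene linear model `expression ~ cluster
#' membership` (one-vs-rest indicator) and calls a gene a marker of the
#' cluster when its FDR-corrected p-value is below `fdr` and its
#' log2(fold change) — the membership coefficient on log2-scale data —
#' exceeds `lfc`. Clusters of size 1 are skipped with a warning.
#'
#' @param expr numeric matrix (log2 scale), genes x cells/samples.
#' @param clusters vector of cluster labels aligned to columns.
#' @param restrict optional subset of column names to which the analysis
#'   is restricted.
#' @param fdr FDR threshold (default 0.05).
#' @param lfc log2 fold-change threshold (default 0.75; strict).
#' @return `data.frame` with columns `cluster`, `feature_id`, `log2FC`,
#'   `p`, `q`, `marker`.
#' @export
detectClusterMarkers <- function(expr, clusters, restrict = NULL,
                                 fdr = 0.05, lfc = 0.75) {
    if (!is.null(restrict)) {
        keep <- colnames(expr) %in% restrict
        expr <- expr[, keep, drop = FALSE]
        clusters <- clusters[keep]
    }
    clusters <- as.character(clusters)
    tab <- table(clusters)
    if (length(tab) < 2L) stop("need >= 2 clusters")
    out <- list()
    for (cl in names(tab)) {
        if (tab[[cl]] < 2L) {
            warning("cluster '", cl, "' has a single member; skipped")
            next
        }
        X <- cbind(1, as.numeric(clusters == cl))
        qrX <- qr(X)
        res <- .olsAllFeatures(expr, X, qrX, 2L)
        q <- bhFDR(res$p)
        out[[cl]] <- data.frame(cluster = cl,
                                feature_id = rownames(expr),
                                log2FC = res$estimate, p = res$p, q = q,
                                marker = q < fdr & res$estimate > lfc,
                                row.names = NULL, stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}
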