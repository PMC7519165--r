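# shared fixtures: everything is generated in code at test time

# a small, fast cohort configuration for structural tests (the default
# cohortConfig() is the full study-sized condition used where power matters)
smallConfig <- function(seed = 1, ...) {
    args <- list(nSubjectsASD = 12, nSubjectsControl = 8,
                 nFeatures = c(mRNA = 60L, miRNA = 30L,
                               meth = 40L, acetyl = 50L),
                 nDiffFeatures = c(mRNA = 10L, miRNA = 5L,
                                   meth = 8L, acetyl = 8L),
                 seed = seed)
    args <- utils::modifyList(args, list(...))
    do.call(cohortConfig, args)
}

# minimal metadata table for matrix-level differential tests
toyMeta <- function(n, paired = FALSE, seed = 1) {
    set.seed(seed)
    if (paired) {
        stopifnot(n %% 2 == 0)
        subj <- rep(sprintf("s%02d", seq_len(n / 2)), each = 2)
        region <- rep(c("Frontal", "Temporal"), n / 2)
    } else {
        subj <- sprintf("s%02d", seq_len(n))
        region <- sample(c("Frontal", "Temporal"), n, replace = TRUE)
    }
    diag <- ifelse(as.integer(factor(subj)) %% 2 == 0, "ASD", "Control")
    data.frame(sample_id = sprintf("samp%02d", seq_len(n)),
               subject_id = subj, diagnosis = diag, region = region,
               age = runif(n, 15, 60),
               sex = sample(c("M", "F"), n, replace = TRUE),
               bank = sample(c("bank1", "bank2"), n, replace = TRUE),
               batch = sample(c("b1", "b2", "b3"), n, replace = TRUE),
               RIN = rnorm(n, 7, 0.8), CET = runif(n, 0.3, 0.6),
               stringsAsFactors = FALSE)
}

# brute-force BH step-up q-values (independent oracle)
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
        val <- min(prev, p[o[i]] * m / i)
        q[o[i]] <- val
        prev <- val
    }
    q
}

# brute-force two-sided Fisher p by enumerating tables with fixed margins
bruteFisher <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1])
    if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
    aRange <- max(0, c1 - r2):min(r1, c1)
    probs <- vapply(aRange, function(a)
        exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)),
        numeric(1))
    pObs <- probs[match(tab[1, 1], aRange)]
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# straight-line reference of the fusion update (independent of snfFuse)
referenceFuse <- function(Ws, K, Tsteps) {
    full <- function(W) {
        P <- W; diag(P) <- 0
        P <- P / (2 * rowSums(P)); diag(P) <- 0.5
        P
    }
    local <- function(W, K) {
        n <- nrow(W)
        S <- matrix(0, n, n)
        for (i in 1:n) {
            w <- W[i, ]; w[i] <- -Inf
            nn <- order(-w)[1:K]
            S[i, nn] <- W[i, nn] / sum(W[i, nn])
        }
        S
    }
    m <- length(Ws)
    P <- lapply(Ws, full)
    S <- lapply(Ws, local, K = K)
    for (t in 1:Tsteps) {
        newP <- vector("list", m)
        for (v in 1:m) {
            other <- Reduce(`+`, P[-v]) / (m - 1)
            Pv <- S[[v]] %*% other %*% t(S[[v]])
            Pv <- (Pv + t(Pv)) / 2
            newP[[v]] <- full(Pv)
        }
        P <- newP
    }
    fused <- Reduce(`+`, P) / m
    (fused + t(fused)) / 2
}

# adjusted Rand index between two labelings (mclust is the oracle where
# available; this closed form keeps the suite self-contained)
ari <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    sumi <- sum(choose(rowSums(tab), 2))
    sumj <- sum(choose(colSums(tab), 2))
    expected <- sumi * sumj / choose(n, 2)
    maxidx <- (sumi + sumj) / 2
    (sumij - expected) / (maxidx - expected)
}
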