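# Independent oracles: deliberately different code paths from the package
# (dense solve()/determinant()/lm()/optimize() instead of the package's
# eigen-rotated algebra), used to cross-check results.

# HWE exact p by full enumeration with closed-form normalization (multinomial
# genotype arrangements over fixed allele counts; no renormalization step)
oracleHwe <- function(n1, n2, n3) {
    n <- n1 + n2 + n3
    nA <- 2 * n1 + n2; nB <- 2 * n3 + n2
    nRare <- min(nA, nB)
    if (nRare == 0) return(1)
    hets <- seq(nRare %% 2, nRare, 2)
    pr <- sapply(hets, function(h) {
        hr <- (nRare - h) / 2
        hc <- n - h - hr
        exp(lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
            h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n))
    })
    pobs <- pr[hets == n2]
    min(1, sum(pr[pr <= pobs * (1 + 1e-12)]))
}

# chi-square asymptotic HWE test
oracleHweChisq <- function(n1, n2, n3) {
    n <- n1 + n2 + n3
    p <- (2 * n1 + n2) / (2 * n)
    e <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
    pchisq(sum((c(n1, n2, n3) - e)^2 / e), 1, lower.tail = FALSE)
}

# dense two-line GRM formula
oracleGrm <- function(d) {
    p <- colMeans(d, na.rm = TRUE) / 2
    keep <- p > 0 & p < 1
    d <- d[, keep, drop = FALSE]; p <- p[keep]
    M <- d - matrix(2 * p, nrow(d), length(p), byrow = TRUE)
    M[is.na(M)] <- 0
    (M %*% t(M)) / (2 * sum(p * (1 - p)))
}

# dense restricted log-likelihood at (sg, se)
oracleRemlLogLik <- function(y, X, K, sg, se) {
    n <- length(y); p <- ncol(X)
    V <- sg * K + se * diag(n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    quad <- as.numeric(t(y) %*% Vi %*% (y - X %*% beta))
    -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) + quad +
            (n - p) * log(2 * pi))
}

# profiled restricted log-likelihood over h2 (total variance closed-form)
oracleRemlProfile <- function(y, X, K, h2) {
    n <- length(y); p <- ncol(X)
    V0 <- h2 * K + (1 - h2) * diag(n)
    Vi <- solve(V0)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    sp <- as.numeric(t(y) %*% Vi %*% (y - X %*% beta)) / (n - p)
    oracleRemlLogLik(y, X, K, h2 * sp, (1 - h2) * sp)
}

# REML by 1-D optimize over h2, dense algebra throughout
oracleReml <- function(y, X, K) {
    opt <- optimize(function(h2) oracleRemlProfile(y, X, K, h2),
                    c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-9)
    h2 <- opt$maximum
    n <- length(y); p <- ncol(X)
    V0 <- h2 * K + (1 - h2) * diag(n)
    Vi <- solve(V0)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    sp <- as.numeric(t(y) %*% Vi %*% (y - X %*% beta)) / (n - p)
    c(sg = h2 * sp, se = (1 - h2) * sp)
}

# GBLUP by direct dense algebra; predicts all samples in Kfull
oracleGblup <- function(y, X, Kfull, sg, se) {
    train <- names(y)[!is.na(y)]
    K <- Kfull[train, train]
    V <- sg * K + se * diag(length(train))
    Vi <- solve(V)
    Xt <- X[train, , drop = FALSE]
    beta <- solve(t(Xt) %*% Vi %*% Xt, t(Xt) %*% Vi %*% y[train])
    resid <- y[train] - as.vector(Xt %*% beta)
    g <- sg * as.vector(Kfull[, train] %*% (Vi %*% resid))
    names(g) <- rownames(Kfull)
    list(beta = as.vector(beta), g = g)
}

# ridge-regression SNP-BLUP: joint MME in (b, alpha), ghat = M alpha
oracleSnpBlup <- function(y, X, d, sg, se) {
    p <- colMeans(d) / 2
    keep <- p > 0 & p < 1
    d <- d[, keep, drop = FALSE]; p <- p[keep]
    M <- d - matrix(2 * p, nrow(d), length(p), byrow = TRUE)
    cscale <- 2 * sum(p * (1 - p))
    lambda <- se * cscale / sg
    q <- ncol(X); m <- ncol(M)
    lhs <- rbind(cbind(t(X) %*% X, t(X) %*% M),
                 cbind(t(M) %*% X, t(M) %*% M + lambda * diag(m)))
    rhs <- c(t(X) %*% y, t(M) %*% y)
    sol <- solve(lhs, rhs)
    as.vector(M %*% sol[(q + 1):(q + m)])
}

# independent greedy reimplementation of windowed pruning: a flat repeat-scan
# over all within-span pairs (no anchored windows), dropping the lower-MAF
# member of the first violating pair (ties: later position) until stable
oracleGreedyPrune <- function(geno, spanBp, cutoff) {
    mk <- markerInfo(geno)
    d <- dosages(geno)
    p <- colMeans(d, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    keep <- rep(TRUE, nrow(mk))
    r2 <- function(j, k) {
        ok <- !is.na(d[, j]) & !is.na(d[, k])
        if (sum(ok) < 2 || sd(d[ok, j]) == 0 || sd(d[ok, k]) == 0)
            return(NA_real_)
        cor(d[ok, j], d[ok, k])^2
    }
    repeat {
        ret <- which(keep)
        removed <- FALSE
        for (a in seq_along(ret)) {
            i <- ret[a]
            for (jj in ret[-seq_len(a)]) {
                if (mk$chrom[jj] != mk$chrom[i] ||
                    mk$pos[jj] - mk$pos[i] > spanBp) break
                v <- r2(i, jj)
                if (!is.na(v) && v > cutoff) {
                    loser <- if (maf[i] < maf[jj]) i
                             else if (maf[jj] < maf[i]) jj
                             else max(i, jj)
                    keep[loser] <- FALSE
                    removed <- TRUE
                    break
                }
            }
            if (removed) break
        }
        if (!removed) break
    }
    which(keep)
}

# single-function CV reimplementation: oracle REML + oracle GBLUP + lm-based
# metrics on the same plan and marker set
oracleCv <- function(y, X, geno, plan, markers = NULL) {
    Kfull <- oracleGrm(if (is.null(markers)) dosages(geno)
                       else dosages(geno)[, markers, drop = FALSE])
    dimnames(Kfull) <- list(names(y), names(y))
    res <- NULL
    for (r in seq_len(plan@nReplicates)) {
        for (f in seq_len(plan@nFolds)) {
            valid <- validationSamples(plan, r, f)
            train <- setdiff(names(y), valid)
            yt <- y; yt[valid] <- NA
            Xt <- X[train, , drop = FALSE]
            vco <- oracleReml(y[train], Xt, Kfull[train, train])
            fit <- oracleGblup(yt, X, Kfull, vco["sg"], vco["se"])
            yc <- y[valid] - as.vector(X[valid, , drop = FALSE] %*% fit$beta)
            g <- fit$g[valid]
            sl <- coef(lm(yc ~ g))[2]
            res <- rbind(res, data.frame(replicate = r, fold = f,
                                         r = cor(g, yc), b = unname(sl)))
        }
    }
    res
}

# per-marker OLS GWAS via lm/qr with a fixed (null-model) residual variance,
# Wald chi-square convention
oracleOlsGwas <- function(y, X, d, sigma2) {
    sapply(seq_len(ncol(d)), function(j) {
        s <- d[, j]
        fit <- lm(y ~ X - 1 + s)
        b <- coef(fit)["s"]
        cu <- chol2inv(qr.R(fit$qr))
        seb <- sqrt(sigma2 * cu[length(coef(fit)), length(coef(fit))])
        c(b = unname(b), se = seb,
          p = unname(pchisq((b / seb)^2, 1, lower.tail = FALSE)))
    })
}
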