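#' Mixed-linear-model association scan (MLMA)
#'
#' Single-marker GWAS with a polygenic background: the model is
#' \code{y = Xb + s a + g + e} with \code{g ~ N(0, sigmaG2 G)} built on the
#' background panel. Variance components are estimated once under the null
#' model (no marker effect) and reused for every marker, as in GCTA's MLMA;
#' each marker is then tested by generalized least squares under
#' \code{V = sigmaG2 G + sigmaE2 I}, with a Wald chi-square(1) p-value. The
#' tested marker is not excluded from the background relationship matrix (no
#' leave-one-chromosome-out); the resulting proximal contamination is mild
#' and conservative.
#'
#' Monomorphic (or fully missing) markers are flagged untestable
#' (\code{tested = FALSE}) rather than dropped. Missing test dosages are
#' mean-imputed.
#'
#' @param y named phenotype vector (NA = excluded)
#' @param X fixed-effect design matrix (default intercept)
#' @param background \linkS4class{GRM}, relationship matrix, or a
#'   \linkS4class{GenotypeData} background panel from which a GRM is built on
#'   the phenotyped samples
#' @param testGenotypes \linkS4class{GenotypeData} of markers to test
#' @param vc optional fixed \linkS4class{VarianceComponents} (skips the null
#'   REML fit); with \code{sigmaG2 = 0} the scan reduces to ordinary least
#'   squares
#' @return data.frame (GWAS table) with columns Chr, SNP, bp, A1, A2, Freq,
#'   b, se, p, negLog10P, tested
#' @export
runMlma <- function(y, X = NULL, background, testGenotypes, vc = NULL) {
    stopifnot(is(testGenotypes, "GenotypeData"))
    if (is.null(X)) {
        X <- matrix(1, length(y), 1, dimnames = list(names(y), "(Intercept)"))
    }
    if (is.null(names(y)))
        stop("y must be named by sample identifiers")
    train <- names(y)[!is.na(y)]
    missG <- setdiff(train, sampleIDs(testGenotypes))
    if (length(missG))
        stop("phenotyped samples absent from the test panel: ",
             paste(utils::head(missG, 5), collapse = ", "))
    if (is(background, "GenotypeData")) {
        missB <- setdiff(train, sampleIDs(background))
        if (length(missB))
            stop("phenotyped samples absent from the background panel: ",
                 paste(utils::head(missB, 5), collapse = ", "))
        background <- computeGrm(background[train, ])
    }
    al <- .alignModel(y, X, background)
    eg <- eigen(al$K, symmetric = TRUE)
    dvals <- pmax(eg$values, 0)
    yr <- as.vector(crossprod(eg$vectors, al$y))
    Xr <- crossprod(eg$vectors, al$X)
    if (is.null(vc)) {
        fit <- .remlCore(yr, Xr, dvals)
        vc <- new("VarianceComponents", sigmaG2 = fit$sigmaG2,
                  sigmaE2 = fit$sigmaE2, logLik = fit$logLik,
                  logLikTrace = fit$trace,
                  nIterations = as.integer(fit$iterations),
                  converged = fit$converged)
    }
    v <- vc@sigmaG2 * dvals + vc@sigmaE2
    w <- 1 / v

    geno <- testGenotypes[al$train, ]
    S <- dosages(geno)
    p <- colMeans(S, na.rm = TRUE) / 2
    tested <- !is.nan(p) & p > 0 & p < 1
    for (j in which(colSums(is.na(S)) > 0))
        S[is.na(S[, j]), j] <- 2 * p[j]
    Sr <- crossprod(eg$vectors, S)

    XtWXi <- solve(crossprod(Xr, Xr * w))
    projW <- function(M) M - Xr %*% (XtWXi %*% crossprod(Xr, M * w))
    yt <- as.vector(projW(matrix(yr)))
    St <- projW(Sr)
    den <- colSums(St * (w * St))
    num <- colSums(St * (w * yt))
    b <- num / den
    se <- sqrt(1 / den)
    chi <- b^2 / se^2
    pval <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
    b[!tested] <- NA; se[!tested] <- NA; pval[!tested] <- NA

    mk <- markerInfo(geno)
    out <- data.frame(Chr = mk$chrom, SNP = mk$id, bp = mk$pos,
                      A1 = mk$a1, A2 = mk$a2, Freq = p,
                      b = b, se = se, p = pval,
                      negLog10P = -log10(pval), tested = tested,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "varianceComponents") <- vc
    out
}

#' Per-fold GWAS for pre-selection (no leakage)
#'
#' Runs \code{runMlma} on the training samples of a cross-validation fold
#' only; validation phenotypes never contribute to marker selection. The
#' background relationship matrix is rebuilt on the training samples.
#'
#' @param y named phenotype vector over all samples
#' @param X fixed-effect design matrix over all samples
#' @param background background panel (see \code{runMlma})
#' @param testGenotypes markers to test
#' @param trainIds training-sample identifiers for this fold
#' @return a GWAS table as from \code{runMlma}
#' @export
gwasPerFold <- function(y, X = NULL, background, testGenotypes, trainIds) {
    yt <- y
    yt[!(names(yt) %in% trainIds)] <- NA
    if (sum(!is.na(yt)) < (if (is.null(X)) 3 else qr(as.matrix(X))$rank + 2))
        stop("training fold too small for REML")
    runMlma(yt, X, background, testGenotypes)
}

#' Genomic-control lambda of a GWAS table
#'
#' Median Wald chi-square divided by the null median 0.4549.
#'
#' @param gwas a GWAS table from \code{runMlma}
#' @return lambda (1 under perfect calibration)
#' @export
genomicControlLambda <- function(gwas) {
    chi <- (gwas$b / gwas$se)^2
    stats::median(chi, na.rm = TRUE) / stats::qchisq(0.5, 1)
}

#' Write a GWAS table in GCTA .mlma-like layout
#'
#' @param gwas GWAS table
#' @param path output file (tab-delimited)
#' @export
writeGwasTable <- function(gwas, path) {
    utils::write.table(
        gwas[, c("Chr", "SNP", "bp", "A1", "A2", "Freq", "b", "se", "p")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
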