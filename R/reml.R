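## REML for the two-component model y = Xb + g + e, g ~ N(0, sigmaG2 * K),
## e ~ N(0, sigmaE2 * I). After one eigendecomposition K = U D U' the rotated
## covariance is diagonal, so every likelihood, gradient and AI evaluation is
## O(n p^2). Iterations are average-information steps with step-halving; when
## no AI step improves the restricted likelihood, a profile step (1-D search
## over the heritability with the closed-form total variance) is taken, so the
## recorded likelihood trajectory is non-decreasing by construction.

# Restricted log-likelihood in the rotated basis. d = eigenvalues of K.
.remlLogLik <- function(sg, se, yr, Xr, d) {
    v <- sg * d + se
    if (any(v <= 0) || !all(is.finite(v))) return(-Inf)
    w <- 1 / v
    XtWX <- crossprod(Xr, Xr * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xr, yr * w)))
    quad <- sum(w * yr * (yr - as.vector(Xr %*% beta)))
    n <- length(yr); p <- ncol(Xr)
    -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + quad +
            (n - p) * log(2 * pi))
}

# Profile candidate: optimize over h2 with the closed-form total variance.
.remlProfileCandidate <- function(yr, Xr, d) {
    n <- length(yr); p <- ncol(Xr)
    prof <- function(h2) {
        u <- h2 * d + (1 - h2)
        w <- 1 / u
        XtWX <- crossprod(Xr, Xr * w)
        ch <- tryCatch(chol(XtWX), error = function(e) NULL)
        if (is.null(ch)) return(-Inf)
        beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xr, yr * w)))
        quad <- sum(w * yr * (yr - as.vector(Xr %*% beta)))
        sp <- quad / (n - p)
        if (sp <= 0) return(-Inf)
        .remlLogLik(h2 * sp, (1 - h2) * sp, yr, Xr, d)
    }
    opt <- stats::optimize(prof, c(1e-8, 1 - 1e-8), maximum = TRUE,
                           tol = 1e-10)
    h2 <- opt$maximum
    u <- h2 * d + (1 - h2)
    w <- 1 / u
    XtWX <- crossprod(Xr, Xr * w)
    beta <- solve(XtWX, crossprod(Xr, yr * w))
    sp <- sum(w * yr * (yr - as.vector(Xr %*% beta))) / (n - p)
    c(h2 * sp, (1 - h2) * sp)
}

.remlCore <- function(yr, Xr, d, maxIterations = 100L, tol = 1e-8) {
    n <- length(yr)
    vy <- stats::var(yr)
    floorv <- 1e-10 * max(vy, .Machine$double.eps)
    theta <- c(0.5 * vy, 0.5 * vy)
    theta <- pmax(theta, floorv)
    cur <- .remlLogLik(theta[1], theta[2], yr, Xr, d)
    trace <- cur
    converged <- FALSE
    iter <- 0L
    while (iter < maxIterations) {
        iter <- iter + 1L
        sg <- theta[1]; se <- theta[2]
        v <- sg * d + se
        w <- 1 / v
        XtWX <- crossprod(Xr, Xr * w)
        XtWXi <- solve(XtWX)
        beta <- XtWXi %*% crossprod(Xr, yr * w)
        Py <- w * (yr - as.vector(Xr %*% beta))
        Pvec <- function(vec) {
            wv <- w * vec
            wv - w * as.vector(Xr %*% (XtWXi %*% crossprod(Xr, wv)))
        }
        trPD <- sum(w * d) -
            sum(XtWXi * crossprod(Xr, Xr * (w * w * d)))
        trPI <- sum(w) - sum(XtWXi * crossprod(Xr, Xr * (w * w)))
        grad <- c(-0.5 * (trPD - sum(d * Py^2)),
                  -0.5 * (trPI - sum(Py^2)))
        PDPy <- Pvec(d * Py)
        PPy <- Pvec(Py)
        AI <- matrix(0, 2, 2)
        AI[1, 1] <- 0.5 * sum((d * Py) * PDPy)
        AI[1, 2] <- AI[2, 1] <- 0.5 * sum(Py * PDPy)
        AI[2, 2] <- 0.5 * sum(Py * PPy)

        accepted <- FALSE
        delta <- tryCatch(solve(AI, grad), error = function(e) NULL)
        if (!is.null(delta) && all(is.finite(delta))) {
            step <- 1
            for (h in 1:20) {
                cand <- pmax(theta + step * delta, floorv)
                ll <- .remlLogLik(cand[1], cand[2], yr, Xr, d)
                if (is.finite(ll) && ll >= cur) {
                    accepted <- TRUE
                    newTheta <- cand; newLl <- ll
                    break
                }
                step <- step / 2
            }
        }
        if (!accepted) {
            cand <- pmax(.remlProfileCandidate(yr, Xr, d), floorv)
            ll <- .remlLogLik(cand[1], cand[2], yr, Xr, d)
            if (is.finite(ll) && ll >= cur) {
                newTheta <- cand; newLl <- ll
            } else {
                newTheta <- theta; newLl <- cur
            }
        }
        trace <- c(trace, newLl)
        dLl <- newLl - cur
        dPar <- max(abs(newTheta - theta)) / max(vy, .Machine$double.eps)
        theta <- newTheta; cur <- newLl
        if (dLl < tol || dPar < tol) { converged <- TRUE; break }
    }
    # final profile polish (never decreases the likelihood)
    cand <- pmax(.remlProfileCandidate(yr, Xr, d), floorv)
    ll <- .remlLogLik(cand[1], cand[2], yr, Xr, d)
    if (is.finite(ll) && ll > cur) {
        theta <- cand; cur <- ll
        trace <- c(trace, ll)
    }
    list(sigmaG2 = theta[1], sigmaE2 = theta[2], logLik = cur,
         trace = trace, iterations = iter, converged = converged)
}

# Align y (named, NA allowed), X and K; drop missing phenotypes. Returns the
# training data plus the eigendecomposition used by REML and MLMA.
.alignModel <- function(y, X, K) {
    Kmat <- if (is(K, "GRM")) grmValues(K) else as.matrix(K)
    if (is.null(names(y))) {
        if (length(y) != nrow(Kmat))
            stop("unnamed y must match the relationship-matrix dimension")
        names(y) <- rownames(Kmat)
    }
    X <- as.matrix(X)
    if (is.null(rownames(X))) rownames(X) <- names(y)
    train <- names(y)[!is.na(y)]
    miss <- setdiff(train, rownames(Kmat))
    if (length(miss))
        stop("samples absent from the relationship matrix: ",
             paste(utils::head(miss, 5), collapse = ", "))
    list(y = y[train], X = X[train, , drop = FALSE],
         K = Kmat[train, train, drop = FALSE], Kfull = Kmat, train = train)
}

#' REML variance components for the GBLUP model
#'
#' Fits \code{y = Xb + g + e} with \code{g ~ N(0, sigmaG2 K)} by restricted
#' maximum likelihood. Iterations are average-information steps with
#' step-halving and a profile-likelihood fallback, so the restricted
#' log-likelihood trajectory is non-decreasing. Variances are floored at
#' \code{1e-10 * var(y)}. Samples with missing phenotype are dropped from y
#' and X (the relationship matrix is subset accordingly).
#'
#' @param y named numeric phenotype vector (NA = unphenotyped)
#' @param X fixed-effect design matrix (rows matching y); default intercept
#' @param K \linkS4class{GRM} or symmetric relationship matrix with sample
#'   dimnames
#' @param maxIterations iteration cap; non-convergence is flagged, not an
#'   error
#' @param tol convergence tolerance on log-likelihood and relative parameter
#'   change
#' @return a \linkS4class{VarianceComponents} object
#' @export
fitReml <- function(y, X = NULL, K, maxIterations = 100L, tol = 1e-8) {
    if (is.null(X)) {
        X <- matrix(1, length(y), 1, dimnames = list(names(y), "(Intercept)"))
    }
    al <- .alignModel(y, X, K)
    n <- length(al$y); p <- qr(al$X)$rank
    if (n < p + 2)
        stop("need at least rank(X) + 2 phenotyped samples")
    if (qr(al$X)$rank < ncol(al$X))
        stop("fixed-effect design matrix is singular")
    eg <- eigen(al$K, symmetric = TRUE)
    dvals <- pmax(eg$values, 0)
    yr <- as.vector(crossprod(eg$vectors, al$y))
    Xr <- crossprod(eg$vectors, al$X)
    fit <- .remlCore(yr, Xr, dvals, maxIterations, tol)
    new("VarianceComponents", sigmaG2 = fit$sigmaG2, sigmaE2 = fit$sigmaE2,
        logLik = fit$logLik, logLikTrace = fit$trace,
        nIterations = as.integer(fit$iterations), converged = fit$converged)
}

#' @rdname heritability
#' @export
setMethod("heritability", "VarianceComponents", function(x) {
    tot <- x@sigmaG2 + x@sigmaE2
    if (tot <= 0) return(NA_real_)
    x@sigmaG2 / tot
})

setMethod("show", "VarianceComponents", function(object) {
    cat(sprintf(
        "VarianceComponents: sigmaG2 = %.4g, sigmaE2 = %.4g (h2 = %.3f)\n",
        object@sigmaG2, object@sigmaE2, heritability(object)))
    cat(sprintf("  logLik = %.4f after %d iterations (converged: %s)\n",
                object@logLik, object@nIterations, object@converged))
})
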