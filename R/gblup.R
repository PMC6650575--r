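#' GBLUP genetic values via Henderson's mixed model equations
#'
#' Solves the mixed model \code{y = Xb + g + e} at the given variance
#' components. Fixed effects are generalized least squares estimates under
#' \code{V = sigmaG2 K + sigmaE2 I} on the phenotyped (training) samples;
#' genetic values are \code{ghat = sigmaG2 K[, train] V^{-1} (y - X bhat)},
#' returned for every sample in the relationship matrix. Unphenotyped samples
#' (NA in y) receive predictions through their relationships with the
#' training set — exactly how a validation fold is predicted in
#' cross-validation.
#'
#' @param y named phenotype vector; NA marks samples to predict only
#' @param X fixed-effect design matrix over all samples in y (default
#'   intercept)
#' @param K \linkS4class{GRM} or relationship matrix covering training and
#'   prediction samples
#' @param vc \linkS4class{VarianceComponents}; if NULL, estimated by
#'   \code{fitReml} first
#' @return a \linkS4class{BlupSolution}
#' @export
solveGblup <- function(y, X = NULL, K, vc = NULL) {
    if (is.null(X)) {
        X <- matrix(1, length(y), 1, dimnames = list(names(y), "(Intercept)"))
    }
    if (is.null(vc)) vc <- fitReml(y, X, K)
    stopifnot(is(vc, "VarianceComponents"))
    if (!is.finite(vc@sigmaG2) || !is.finite(vc@sigmaE2))
        stop("variance components must be finite")
    al <- .alignModel(y, X, K)
    n <- length(al$y)
    V <- vc@sigmaG2 * al$K + vc@sigmaE2 * diag(n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch))
        stop("mixed-model system is singular; consider adding a small value ",
             "to the diagonal of the relationship matrix")
    Vi <- chol2inv(ch)
    XtVi <- crossprod(al$X, Vi)
    beta <- tryCatch(solve(XtVi %*% al$X, XtVi %*% al$y),
                     error = function(e)
                         stop("fixed-effect design matrix is singular"))
    resid <- al$y - as.vector(al$X %*% beta)
    g <- vc@sigmaG2 *
        as.vector(al$Kfull[, al$train, drop = FALSE] %*% (Vi %*% resid))
    names(g) <- rownames(al$Kfull)
    betaVec <- as.vector(beta)
    names(betaVec) <- colnames(al$X)
    new("BlupSolution", fixedEffects = betaVec, geneticValues = g,
        varianceComponents = vc)
}

#' @rdname geneticValues
#' @export
setMethod("geneticValues", "BlupSolution", function(x) x@geneticValues)

#' @rdname fixedEffects
#' @export
setMethod("fixedEffects", "BlupSolution", function(x) x@fixedEffects)

setMethod("show", "BlupSolution", function(object) {
    cat("BlupSolution:", length(object@geneticValues), "genetic values;",
        length(object@fixedEffects), "fixed effect(s)\n")
    cat(sprintf("  h2 used = %.3f\n",
                heritability(object@varianceComponents)))
})
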