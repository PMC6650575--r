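#' Build a repeated cross-validation plan
#'
#' Each replicate assigns every sample to exactly one validation fold,
#' uniformly at random, with fold sizes differing by at most one. The
#' conventional design for predictive-ability evaluation is 10 replicates of
#' 5-fold cross-validation.
#'
#' @param samples sample identifiers
#' @param nReplicates number of replicates (default 10)
#' @param nFolds folds per replicate (default 5)
#' @param seed integer seed; the plan is reproducible from it
#' @return a \linkS4class{CvPlan}
#' @export
makeCvPlan <- function(samples, nReplicates = 10L, nFolds = 5L, seed = 1L) {
    n <- length(samples)
    if (nFolds > n) stop("more folds than samples")
    withSeed(seed, {
        assignments <- lapply(seq_len(nReplicates), function(r) {
            a <- sample(rep_len(seq_len(nFolds), n))
            names(a) <- samples
            a
        })
        new("CvPlan", assignments = assignments,
            nReplicates = as.integer(nReplicates),
            nFolds = as.integer(nFolds), seed = as.integer(seed))
    })
}

#' Validation samples of one fold
#'
#' @param plan a CvPlan
#' @param replicate,fold indices
#' @return character vector of sample ids in the validation fold
#' @export
validationSamples <- function(plan, replicate, fold) {
    a <- plan@assignments[[replicate]]
    names(a)[a == fold]
}

setMethod("show", "CvPlan", function(object) {
    cat("CvPlan:", object@nReplicates, "replicate(s) x", object@nFolds,
        "folds over", length(object@assignments[[1]]), "samples (seed",
        object@seed, ")\n")
})

#' Phenotypes corrected for fixed effects estimated on the training set
#'
#' Returns \code{y - X bhat} using fixed-effect estimates from the
#' training-set model only, so validation phenotypes never influence their
#' own correction. If the estimates carry an NA for a design column that is
#' non-zero in some row (a factor level unseen in training), an error names
#' that column.
#'
#' @param y phenotype vector
#' @param X design matrix (rows matching y)
#' @param trainingFit a \linkS4class{BlupSolution} from the training fold, or
#'   a named coefficient vector
#' @return corrected phenotype vector
#' @export
correctedPhenotype <- function(y, X, trainingFit) {
    beta <- if (is(trainingFit, "BlupSolution"))
        fixedEffects(trainingFit) else trainingFit
    X <- as.matrix(X)
    if (ncol(X) != length(beta))
        stop("design matrix and coefficient length differ")
    bad <- is.na(beta)
    if (any(bad)) {
        used <- colSums(abs(X[, bad, drop = FALSE]) > 0) > 0
        if (any(used))
            stop("fixed-effect level(s) unseen in training: ",
                 paste(colnames(X)[bad][used], collapse = ", "))
        beta[bad] <- 0
    }
    as.vector(y - X %*% beta)
}

#' Prediction accuracy and bias
#'
#' Accuracy is the Pearson correlation between predicted genetic values and
#' fixed-effect-corrected phenotypes. Bias is the slope of the least-squares
#' regression of the corrected phenotype on the prediction,
#' \code{b = cov(y, ghat) / var(ghat)}; b = 1 means unbiased.
#'
#' @param gHat predicted genetic values
#' @param yCorrected corrected phenotypes (same samples)
#' @return list with elements \code{r} and \code{b} (NA, flagged by a
#'   warning, if either vector is constant)
#' @export
accuracyAndBias <- function(gHat, yCorrected) {
    if (length(gHat) != length(yCorrected))
        stop("vectors differ in length")
    ok <- !is.na(gHat) & !is.na(yCorrected)
    if (sum(ok) < 3) stop("need at least 3 pairs")
    g <- gHat[ok]; yc <- yCorrected[ok]
    if (stats::sd(g) == 0 || stats::sd(yc) == 0) {
        warning("constant predictions or phenotypes: accuracy undefined")
        return(list(r = NA_real_, b = NA_real_))
    }
    list(r = stats::cor(g, yc),
         b = stats::cov(yc, g) / stats::var(g))
}

#' Repeated cross-validated genomic prediction
#'
#' For every replicate and fold: variance components are estimated by REML on
#' the training samples only; genetic values of the validation fold are
#' predicted by GBLUP through the relationship matrix; accuracy and bias are
#' computed on the validation fold against phenotypes corrected with the
#' training fixed-effect estimates. Validation phenotypes are never seen by
#' any training-stage computation.
#'
#' With \code{selection} supplied, the marker set is recomputed within each
#' training fold: an MLMA scan on the training samples (background
#' relationship matrix from \code{selection$background}) feeds
#' \code{selectSignificantRegions}; \code{selection$scheme} chooses the raw
#' selected set ("regions") or the near-duplicate-pruned set ("s3").
#'
#' @param y named phenotype vector
#' @param X fixed-effect design matrix over the same samples (default
#'   intercept)
#' @param x GenotypeData panel
#' @param plan a \linkS4class{CvPlan}
#' @param markers optional fixed marker subset (indices or ids)
#' @param selection optional list(spec = SelectionSpec, background =
#'   GenotypeData or marker indices into \code{x}, scheme = "regions"|"s3")
#' @param label marker-set label recorded in the report
#' @return data.frame (CV report): label, replicate, fold, n, r, b
#' @export
runCv <- function(y, X = NULL, x, plan, markers = NULL, selection = NULL,
                  label = "all") {
    stopifnot(is(x, "GenotypeData"), is(plan, "CvPlan"))
    if (is.null(X)) {
        X <- matrix(1, length(y), 1, dimnames = list(names(y), "(Intercept)"))
    }
    if (is.null(names(y))) stop("y must be named by sample identifiers")
    if (is.null(rownames(X))) rownames(X) <- names(y)
    grmFull <- if (is.null(selection))
        computeGrm(x, markers) else NULL
    bg <- NULL
    if (!is.null(selection)) {
        bg <- selection$background
        if (!is(bg, "GenotypeData")) bg <- x[, bg]
    }
    out <- list()
    for (r in seq_len(plan@nReplicates)) {
        for (f in seq_len(plan@nFolds)) {
            valid <- validationSamples(plan, r, f)
            train <- setdiff(names(y), valid)
            yTrain <- y
            yTrain[valid] <- NA
            if (is.null(selection)) {
                grm <- grmFull
            } else {
                gw <- gwasPerFold(y, X, bg, x, train)
                set <- switch(selection$scheme %||% "regions",
                    regions = selectedMarkers(
                        selectSignificantRegions(gw, selection$spec, x)),
                    s3 = s3MarkerSet(gw, selection$spec, x))
                if (length(set) < 2)
                    stop(sprintf(
                        "replicate %d fold %d: selected marker set too small",
                        r, f))
                grm <- computeGrm(x, set)
            }
            vc <- fitReml(yTrain, X, grm)
            blup <- solveGblup(yTrain, X, grm, vc)
            yc <- correctedPhenotype(y[valid], X[valid, , drop = FALSE], blup)
            ab <- accuracyAndBias(geneticValues(blup)[valid], yc)
            out[[length(out) + 1]] <- data.frame(
                label = label, replicate = r, fold = f,
                n = length(valid), r = ab$r, b = ab$b)
        }
    }
    do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a CV report
#'
#' Means with two spreads: the SD of replicate means (the conventional
#' parenthesized SD) and the SD over all fold values.
#'
#' @param report data.frame from \code{runCv} (possibly rbind-ed over
#'   marker-set labels)
#' @return data.frame per label: meanR, sdReplicateR, sdFoldR, meanB,
#'   sdReplicateB, sdFoldB
#' @export
cvSummary <- function(report) {
    do.call(rbind, lapply(split(report, report$label), function(g) {
        repR <- tapply(g$r, g$replicate, mean)
        repB <- tapply(g$b, g$replicate, mean)
        data.frame(label = g$label[1],
                   meanR = mean(g$r), sdReplicateR = stats::sd(repR),
                   sdFoldR = stats::sd(g$r),
                   meanB = mean(g$b), sdReplicateB = stats::sd(repB),
                   sdFoldB = stats::sd(g$b))
    }))
}

#' Genotype-recovery accuracy at masked markers
#'
#' Scores an imputed (or otherwise reconstructed) panel against the truth at
#' deliberately masked markers: the correlation between imputed and true
#' dosages per sample (across that sample's masked genotypes) and per masked
#' marker (across samples). Undefined correlations (zero variance on either
#' side) are flagged and excluded from the means, with counts retained.
#'
#' @param imputed GenotypeData after reconstruction
#' @param truth GenotypeData with the true dosages (same samples/markers)
#' @param mask integer indices of the masked markers
#' @return an \linkS4class{ImputationAccuracy}
#' @export
scoreImputation <- function(imputed, truth, mask) {
    stopifnot(is(imputed, "GenotypeData"), is(truth, "GenotypeData"))
    if (!length(mask)) stop("mask must be non-empty")
    if (!identical(dim(dosages(imputed)), dim(dosages(truth))))
        stop("imputed and truth panels differ in dimension")
    di <- dosages(imputed)[, mask, drop = FALSE]
    dt <- dosages(truth)[, mask, drop = FALSE]
    corSafe <- function(a, b) {
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < 2 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
            return(NA_real_)
        stats::cor(a[ok], b[ok])
    }
    perSample <- vapply(seq_len(nrow(di)),
                        function(i) corSafe(di[i, ], dt[i, ]), 0.0)
    names(perSample) <- rownames(di)
    perMarker <- vapply(seq_len(ncol(di)),
                        function(j) corSafe(di[, j], dt[, j]), 0.0)
    names(perMarker) <- colnames(di)
    new("ImputationAccuracy", perSample = perSample, perMarker = perMarker,
        nUndefinedSample = sum(is.na(perSample)),
        nUndefinedMarker = sum(is.na(perMarker)))
}

setMethod("show", "ImputationAccuracy", function(object) {
    cat(sprintf(
        "ImputationAccuracy: per-sample %.3f +- %.3f (%d undefined); per-marker %.3f +- %.3f (%d undefined)\n",
        mean(object@perSample, na.rm = TRUE),
        stats::sd(object@perSample, na.rm = TRUE), object@nUndefinedSample,
        mean(object@perMarker, na.rm = TRUE),
        stats::sd(object@perMarker, na.rm = TRUE), object@nUndefinedMarker))
})

#' Per-sample correlations of an ImputationAccuracy
#' @param x ImputationAccuracy
#' @export
perSampleAccuracy <- function(x) x@perSample

#' Per-marker correlations of an ImputationAccuracy
#' @param x ImputationAccuracy
#' @export
perMarkerAccuracy <- function(x) x@perMarker
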