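#' @import methods
NULL

## Central containers. Dosages count the A1/ALT allele (0, 1, 2); missing
## genotypes are NA. Marker maps are kept sorted by (chrom, pos) and positions
## must be strictly increasing within a chromosome.

#' GenotypeData: individuals x markers dosage matrix with a marker map
#'
#' Rows are samples (rownames are the sample identifiers), columns are markers.
#' The marker map holds, per marker: \code{id}, \code{chrom}, \code{pos} (bp,
#' 1-based), \code{a1} (the counted allele) and \code{a2}.
#'
#' @slot dosages numeric matrix of allele dosages in \{0, 1, 2, NA\}
#' @slot markers data.frame with columns id, chrom, pos, a1, a2
#' @exportClass GenotypeData
setClass("GenotypeData", slots = c(dosages = "matrix", markers = "data.frame"))

setValidity("GenotypeData", function(object) {
    d <- object@dosages
    mk <- object@markers
    msg <- character()
    need <- c("id", "chrom", "pos", "a1", "a2")
    if (!all(need %in% names(mk)))
        return(paste("marker map must have columns:", paste(need, collapse = ", ")))
    if (nrow(mk) != ncol(d))
        msg <- c(msg, "marker map rows must match dosage columns")
    if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
        msg <- c(msg, "sample identifiers (rownames) must be present and unique")
    if (anyDuplicated(mk$id))
        msg <- c(msg, "marker identifiers must be unique")
    bad <- d[!is.na(d) & !(d %in% c(0, 1, 2))]
    if (length(bad))
        msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    for (ch in unique(mk$chrom)) {
        p <- mk$pos[mk$chrom == ch]
        if (any(diff(p) <= 0)) {
            msg <- c(msg, sprintf(
                "positions must be strictly increasing within chromosome %s", ch))
            break
        }
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' QC thresholds for marker and sample filtering
#'
#' @slot minSnpCallRate minimum per-marker call rate
#' @slot minSampleCallRate minimum per-sample call rate
#' @slot minMaf minimum minor allele frequency
#' @slot minHweP minimum Hardy-Weinberg exact-test p-value
#' @exportClass QcThresholds
setClass("QcThresholds", slots = c(
    minSnpCallRate = "numeric", minSampleCallRate = "numeric",
    minMaf = "numeric", minHweP = "numeric"))

setValidity("QcThresholds", function(object) {
    v <- c(object@minSnpCallRate, object@minSampleCallRate,
           object@minMaf, object@minHweP)
    if (length(v) != 4 || any(!is.finite(v)) || any(v < 0) || any(v > 1))
        "all thresholds must be single values in [0, 1]" else TRUE
})

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = M M' / (2 * sum p_i (1 - p_i)) with M the column-centered dosage matrix.
#'
#' @slot values n x n symmetric relationship matrix (dimnames = samples)
#' @slot scale the denominator 2 * sum p_i (1 - p_i)
#' @slot nMarkersUsed number of polymorphic markers entering the matrix
#' @slot frequencies counted-allele frequencies used for centering
#' @exportClass GRM
setClass("GRM", slots = c(
    values = "matrix", scale = "numeric",
    nMarkersUsed = "integer", frequencies = "numeric"))

setValidity("GRM", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
    if (object@scale <= 0) msg <- c(msg, "scale must be positive")
    if (is.null(rownames(v))) msg <- c(msg, "samples must be named")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' REML variance components for the two-component GBLUP model
#'
#' @slot sigmaG2 additive genetic variance
#' @slot sigmaE2 residual variance
#' @slot logLik restricted log-likelihood at the optimum
#' @slot logLikTrace restricted log-likelihood after each iteration
#' @slot nIterations iterations used
#' @slot converged convergence flag
#' @exportClass VarianceComponents
setClass("VarianceComponents", slots = c(
    sigmaG2 = "numeric", sigmaE2 = "numeric", logLik = "numeric",
    logLikTrace = "numeric", nIterations = "integer", converged = "logical"))

setValidity("VarianceComponents", function(object) {
    if (object@sigmaG2 < 0 || object@sigmaE2 < 0)
        "variances must be non-negative" else TRUE
})

#' GBLUP solution: fixed-effect estimates and genetic values
#'
#' Genetic values are returned for every sample in the relationship matrix,
#' including unphenotyped (validation) samples, whose values come through the
#' off-diagonal relationships.
#'
#' @slot fixedEffects named vector of fixed-effect estimates
#' @slot geneticValues named vector of predicted genetic values
#' @slot varianceComponents the VarianceComponents used
#' @exportClass BlupSolution
setClass("BlupSolution", slots = c(
    fixedEffects = "numeric", geneticValues = "numeric",
    varianceComponents = "VarianceComponents"))

#' Simulation configuration for the pedigreed population generator
#'
#' Defaults emulate the design of a single-generation broiler mating scheme:
#' 30 sires each mated to 12 dams (360 dams), offspring raised in six pens,
#' a dense "WGS" panel of which an evenly spaced fraction forms the chip.
#'
#' @exportClass SimConfig
setClass("SimConfig", slots = c(
    nSires = "integer", nDams = "integer", offspringPerDam = "integer",
    nChromosomes = "integer", markersPerChromosome = "integer",
    chromosomeLengthBp = "numeric", founderLdDecay = "numeric",
    nQtl = "integer", heritability = "numeric",
    nPens = "integer", penEffectSd = "numeric",
    chipFraction = "numeric", imputationErrorRate = "numeric",
    qtlOnChip = "logical", qtlEffectDist = "character", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    cnt <- c(object@nSires, object@nDams, object@offspringPerDam,
             object@nChromosomes, object@markersPerChromosome, object@nPens)
    if (any(cnt < 1)) msg <- c(msg, "all counts must be >= 1")
    if (object@nQtl < 0) msg <- c(msg, "nQtl must be >= 0")
    if (object@nQtl > 0 &&
        (object@heritability <= 0 || object@heritability >= 1))
        msg <- c(msg, "heritability must be in (0, 1) when nQtl >= 1")
    if (object@chipFraction <= 0 || object@chipFraction > 1)
        msg <- c(msg, "chipFraction must be in (0, 1]")
    if (object@imputationErrorRate < 0 || object@imputationErrorRate > 1)
        msg <- c(msg, "imputationErrorRate must be in [0, 1]")
    if (object@nQtl > object@nChromosomes * object@markersPerChromosome)
        msg <- c(msg, "nQtl exceeds the number of markers")
    if (!object@qtlEffectDist %in% c("normal", "gamma"))
        msg <- c(msg, "qtlEffectDist must be 'normal' or 'gamma'")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Ground truth emitted by the simulator
#'
#' @slot breedingValues named true breeding values
#' @slot qtl data.frame of QTL marker index, id and effect size
#' @slot realizedHeritability realized var(BV) / var(y)
#' @slot pens named factor of pen assignments
#' @exportClass TruthSet
setClass("TruthSet", slots = c(
    breedingValues = "numeric", qtl = "data.frame",
    realizedHeritability = "numeric", pens = "factor"))

#' Cross-validation plan: repeated random fold assignments
#'
#' @slot assignments list (one per replicate) of named integer fold labels
#' @slot nReplicates number of replicates
#' @slot nFolds folds per replicate
#' @slot seed seed the plan was drawn from
#' @exportClass CvPlan
setClass("CvPlan", slots = c(
    assignments = "list", nReplicates = "integer",
    nFolds = "integer", seed = "integer"))

setValidity("CvPlan", function(object) {
    for (a in object@assignments) {
        sz <- tabulate(a, nbins = object@nFolds)
        if (sum(sz) != length(a) || diff(range(sz)) > 1)
            return("each replicate must partition all samples into folds of near-equal size")
    }
    TRUE
})

#' Partition of a marker panel into selected and remaining variants
#'
#' @slot selected marker indices inside significant regions
#' @slot remaining the complement
#' @slot regions data.frame (chrom, start, end) of merged significant regions
#' @exportClass MarkerPartition
setClass("MarkerPartition", slots = c(
    selected = "integer", remaining = "integer", regions = "data.frame"))

setValidity("MarkerPartition", function(object) {
    if (length(intersect(object@selected, object@remaining)))
        return("selected and remaining must be disjoint")
    TRUE
})

#' Imputation (genotype-recovery) accuracy at masked genotypes
#'
#' @slot perSample correlation per sample across its masked genotypes
#' @slot perMarker correlation per masked marker across samples
#' @slot nUndefinedSample samples with undefined correlation (zero variance)
#' @slot nUndefinedMarker masked markers with undefined correlation
#' @exportClass ImputationAccuracy
setClass("ImputationAccuracy", slots = c(
    perSample = "numeric", perMarker = "numeric",
    nUndefinedSample = "integer", nUndefinedMarker = "integer"))
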