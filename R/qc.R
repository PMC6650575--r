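#' Quality-control thresholds
#'
#' Defaults are the conventional post-imputation filters for dense poultry
#' panels: SNP call rate > 95%, individual call rate > 97%, MAF > 0.5% and
#' Hardy-Weinberg exact-test p > 1e-6. The pre-imputation convention uses a
#' 97% SNP call rate instead; both are expressible here.
#'
#' @param minSnpCallRate minimum per-marker call rate (default 0.95)
#' @param minSampleCallRate minimum per-sample call rate (default 0.97)
#' @param minMaf minimum minor allele frequency (default 0.005)
#' @param minHweP minimum HWE exact p-value (default 1e-6)
#' @return a \linkS4class{QcThresholds} object
#' @export
QcThresholds <- function(minSnpCallRate = 0.95, minSampleCallRate = 0.97,
                         minMaf = 0.005, minHweP = 1e-6) {
    new("QcThresholds", minSnpCallRate = minSnpCallRate,
        minSampleCallRate = minSampleCallRate,
        minMaf = minMaf, minHweP = minHweP)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test (Wigginton-style, plain p-value, no mid-p): with the
#' allele counts fixed, the p-value sums the probabilities of all heterozygote
#' counts of the same parity that are no more probable than the observed one.
#'
#' @param nHom1 count of homozygotes for allele 1
#' @param nHet heterozygote count
#' @param nHom2 count of homozygotes for allele 2
#' @return exact p-value in (0, 1]
#' @examples
#' hweExactTest(3, 5, 2)
#' hweExactTest(0, 0, 10)  # monomorphic: 1
#' @export
hweExactTest <- function(nHom1, nHet, nHom2) {
    if (any(c(nHom1, nHet, nHom2) < 0)) stop("genotype counts must be >= 0")
    n <- nHom1 + nHet + nHom2
    if (n <= 0) stop("total genotype count must be > 0")
    nA <- 2 * nHom1 + nHet
    nB <- 2 * nHom2 + nHet
    nRare <- min(nA, nB)
    if (nRare == 0) return(1.0)
    hets <- seq.int(nRare %% 2, nRare, by = 2)
    # log P(het | allele counts) up to a constant: multinomial arrangements of
    # genotypes over the fixed allele counts
    homR <- (nRare - hets) / 2
    homC <- (n - hets - homR)
    lp <- lfactorial(n) - lfactorial(homR) - lfactorial(hets) -
        lfactorial(homC) + hets * log(2)
    lp <- lp - max(lp)
    pr <- exp(lp) / sum(exp(lp))
    pObs <- pr[match(nHet, hets)]
    min(1.0, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

#' Apply quality-control filters to a genotype panel
#'
#' Filters are applied in a fixed, logged order: (1) per-marker call rate,
#' (2) per-sample call rate, (3) MAF on the surviving samples, (4) HWE exact
#' test on the surviving samples. MAF is \code{min(p, 1-p)} of the counted
#' allele. The order matters because MAF and HWE depend on which samples
#' survive; it is recorded in the returned log.
#'
#' @param x GenotypeData
#' @param thresholds a \linkS4class{QcThresholds} object
#' @return list with elements \code{genotypes} (filtered GenotypeData),
#'   \code{log} (data.frame: step, removed, retained) and \code{removedIds}
#'   (list of removed marker/sample ids per step)
#' @export
applyQc <- function(x, thresholds = QcThresholds()) {
    stopifnot(is(x, "GenotypeData"), is(thresholds, "QcThresholds"))
    removedIds <- list()
    log <- data.frame(step = character(), removed = integer(),
                      retained = integer())
    note <- function(step, removed, retained) {
        log <<- rbind(log, data.frame(step = step, removed = length(removed),
                                      retained = retained))
        removedIds[[step]] <<- removed
    }

    cr <- callRates(x)
    dropM <- markerInfo(x)$id[cr$marker < thresholds@minSnpCallRate]
    x <- x[, setdiff(markerInfo(x)$id, dropM)]
    note("snp_call_rate", dropM, nMarkers(x))
    if (nMarkers(x) == 0) stop("all markers removed by the SNP call-rate filter")

    cr <- callRates(x)
    dropS <- sampleIDs(x)[cr$sample < thresholds@minSampleCallRate]
    x <- x[setdiff(sampleIDs(x), dropS), ]
    note("sample_call_rate", dropS, nSamples(x))
    if (nSamples(x) == 0) stop("all samples removed by the call-rate filter")

    p <- alleleFrequencies(x)
    maf <- pmin(p, 1 - p)
    dropM <- markerInfo(x)$id[is.nan(maf) | maf < thresholds@minMaf]
    x <- x[, setdiff(markerInfo(x)$id, dropM)]
    note("maf", dropM, nMarkers(x))
    if (nMarkers(x) == 0) stop("all markers removed by the MAF filter")

    d <- dosages(x)
    hweP <- vapply(seq_len(ncol(d)), function(j) {
        g <- d[, j][!is.na(d[, j])]
        hweExactTest(sum(g == 2), sum(g == 1), sum(g == 0))
    }, 0.0)
    dropM <- markerInfo(x)$id[hweP < thresholds@minHweP]
    x <- x[, setdiff(markerInfo(x)$id, dropM)]
    note("hwe", dropM, nMarkers(x))
    if (nMarkers(x) == 0) stop("all markers removed by the HWE filter")

    list(genotypes = x, log = log, removedIds = removedIds)
}

#' Write a QC log as a machine-readable delimited summary
#'
#' @param qc result of \code{applyQc}
#' @param path output file
#' @export
writeQcLog <- function(qc, path) {
    utils::write.table(qc$log, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
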