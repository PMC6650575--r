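#' Simulation configuration
#'
#' Defaults emulate a single hatch of a pedigreed broiler breeding scheme:
#' 30 sires mated to 360 dams (half/full-sib families), offspring housed in
#' six pens, genotyped on a dense "WGS" panel of which an evenly spaced
#' fraction forms the lower-density chip. Founder haplotypes carry first-order
#' (adjacent-marker) LD controlled by \code{founderLdDecay}; offspring are
#' gene-dropped with Haldane crossovers at 1 cM/Mb.
#'
#' @param nSires,nDams,offspringPerDam mating design counts
#' @param nChromosomes,markersPerChromosome,chromosomeLengthBp genome layout
#' @param founderLdDecay latent AR(1) correlation between adjacent markers on
#'   a founder haplotype, in [0, 1)
#' @param nQtl number of additive QTL (0 allowed: pure noise trait)
#' @param heritability target proportion of phenotypic (non-pen) variance
#'   explained by the QTL, in (0, 1)
#' @param nPens,penEffectSd categorical pen effect: number of levels and the
#'   SD of level effects, in phenotypic-SD units (genetic + residual variance
#'   is scaled to 1)
#' @param chipFraction fraction of markers designated "chip", in (0, 1]
#' @param imputationErrorRate default per-genotype corruption probability
#' @param qtlOnChip if FALSE (default) QTL are drawn from WGS-only markers so
#'   the chip tags but does not contain the causal variants
#' @param qtlEffectDist "normal" (default) or "gamma" (few large effects)
#' @param seed integer seed
#' @return a \linkS4class{SimConfig} object
#' @export
simConfig <- function(nSires = 30L, nDams = 360L, offspringPerDam = 1L,
                      nChromosomes = 5L, markersPerChromosome = 200L,
                      chromosomeLengthBp = 5e7, founderLdDecay = 0.9,
                      nQtl = 50L, heritability = 0.3,
                      nPens = 6L, penEffectSd = 0.5,
                      chipFraction = 0.1, imputationErrorRate = 0.03,
                      qtlOnChip = FALSE, qtlEffectDist = "normal",
                      seed = 1L) {
    new("SimConfig",
        nSires = as.integer(nSires), nDams = as.integer(nDams),
        offspringPerDam = as.integer(offspringPerDam),
        nChromosomes = as.integer(nChromosomes),
        markersPerChromosome = as.integer(markersPerChromosome),
        chromosomeLengthBp = chromosomeLengthBp,
        founderLdDecay = founderLdDecay, nQtl = as.integer(nQtl),
        heritability = heritability, nPens = as.integer(nPens),
        penEffectSd = penEffectSd, chipFraction = chipFraction,
        imputationErrorRate = imputationErrorRate,
        qtlOnChip = qtlOnChip, qtlEffectDist = qtlEffectDist,
        seed = as.integer(seed))
}

# Founder haplotypes with first-order LD: latent AR(1) Gaussian thresholded at
# the per-marker allele frequency. Returns nHap x m 0/1 matrix.
.founderHaplotypes <- function(nHap, p, rho) {
    m <- length(p)
    z <- matrix(0, nHap, m)
    z[, 1] <- stats::rnorm(nHap)
    if (m > 1)
        for (j in 2:m)
            z[, j] <- rho * z[, j - 1] +
                sqrt(1 - rho^2) * stats::rnorm(nHap)
    thr <- stats::qnorm(p)
    (z < rep(thr, each = nHap)) * 1L
}

# One gamete from a parent's two haplotypes: Haldane model, crossover count
# Poisson in the map length (1 cM/Mb), positions uniform.
.meiosis <- function(hap1, hap2, posBp) {
    lenM <- max(posBp) * 1e-8
    nx <- stats::rpois(1, lenM)
    xpos <- sort(stats::runif(nx, 0, max(posBp)))
    seg <- findInterval(posBp, xpos)
    use1 <- (seg + stats::rbinom(1, 1, 0.5)) %% 2 == 0
    ifelse(use1, hap1, hap2)
}

# Evenly spaced chip subset of size ceiling(f * m), spanning both panel ends
.chipIndices <- function(m, fraction) {
    nChip <- ceiling(fraction * m)
    if (nChip >= m) return(seq_len(m))
    as.integer(round(seq(1, m, length.out = nChip)))
}

#' Simulate a pedigreed population with LD, QTL and pen effects
#'
#' Founder haplotypes are drawn with first-order LD; offspring are produced by
#' gene-dropping with Haldane crossovers. The phenotype is
#' \code{y = pen + sum(dosage * effect) + e}, with QTL effects rescaled so the
#' realized breeding-value variance equals \code{heritability} and residual
#' variance \code{1 - heritability} (total non-pen variance 1). By default QTL
#' are placed on WGS-only markers so the chip panel tags, but does not
#' contain, the causal variants. Deterministic under the config seed.
#'
#' @param cfg a \linkS4class{SimConfig} object
#' @return list with \code{genotypes} (offspring \linkS4class{GenotypeData},
#'   WGS density), \code{phenotypes} (data.frame: sample, y, pen),
#'   \code{truth} (\linkS4class{TruthSet}), \code{founders} (parental
#'   \linkS4class{GenotypeData}) and \code{pedigree} (data.frame: id, sire,
#'   dam)
#' @export
simulatePopulation <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    withSeed(cfg@seed, {
        mpc <- cfg@markersPerChromosome
        nC <- cfg@nChromosomes
        m <- nC * mpc

        mk <- do.call(rbind, lapply(seq_len(nC), function(ch) {
            pos <- sort(sample.int(cfg@chromosomeLengthBp, mpc))
            data.frame(id = sprintf("c%02dm%04d", ch, seq_len(mpc)),
                       chrom = as.character(ch), pos = pos,
                       a1 = "A", a2 = "G")
        }))
        p0 <- stats::runif(m, 0.05, 0.95)

        nF <- cfg@nSires + cfg@nDams
        # haplotypes stored per chromosome: 2 per founder, sires then dams
        hap <- lapply(seq_len(nC), function(ch) {
            idx <- (ch - 1) * mpc + seq_len(mpc)
            list(h1 = .founderHaplotypes(nF, p0[idx], cfg@founderLdDecay),
                 h2 = .founderHaplotypes(nF, p0[idx], cfg@founderLdDecay))
        })

        sireOfDam <- rep(seq_len(cfg@nSires), length.out = cfg@nDams)
        nOff <- cfg@nDams * cfg@offspringPerDam
        dam <- rep(seq_len(cfg@nDams), each = cfg@offspringPerDam)
        sire <- sireOfDam[dam]
        offIds <- sprintf("ind%05d", seq_len(nOff))
        founderIds <- c(sprintf("sire%03d", seq_len(cfg@nSires)),
                        sprintf("dam%03d", seq_len(cfg@nDams)))

        offD <- matrix(0, nOff, m, dimnames = list(offIds, mk$id))
        for (ch in seq_len(nC)) {
            idx <- (ch - 1) * mpc + seq_len(mpc)
            pos <- mk$pos[idx]
            h1 <- hap[[ch]]$h1; h2 <- hap[[ch]]$h2
            for (k in seq_len(nOff)) {
                s <- sire[k]; d <- cfg@nSires + dam[k]
                offD[k, idx] <-
                    .meiosis(h1[s, ], h2[s, ], pos) +
                    .meiosis(h1[d, ], h2[d, ], pos)
            }
        }
        founderD <- do.call(cbind, lapply(seq_len(nC), function(ch)
            hap[[ch]]$h1 + hap[[ch]]$h2))
        dimnames(founderD) <- list(founderIds, mk$id)

        geno <- GenotypeData(offD, mk)          # sorts by (chrom, pos)
        founders <- GenotypeData(founderD, mk)

        chipIdx <- .chipIndices(m, cfg@chipFraction)
        qtlPool <- if (cfg@qtlOnChip) seq_len(m) else setdiff(seq_len(m), chipIdx)
        if (cfg@nQtl > length(qtlPool))
            stop(sprintf("nQtl = %d exceeds the %d available markers",
                         cfg@nQtl, length(qtlPool)))

        d <- dosages(geno)
        if (cfg@nQtl > 0) {
            qtlIdx <- sort(sample(qtlPool, cfg@nQtl))
            eff <- switch(cfg@qtlEffectDist,
                normal = stats::rnorm(cfg@nQtl),
                gamma = sample(c(-1, 1), cfg@nQtl, TRUE) *
                    stats::rgamma(cfg@nQtl, shape = 0.4, scale = 1.66))
            bv <- as.vector(d[, qtlIdx, drop = FALSE] %*% eff)
            vb <- stats::var(bv)
            if (vb > 0) {
                sc <- sqrt(cfg@heritability / vb)
                eff <- eff * sc
                bv <- bv * sc
            }
            residSd <- sqrt(max(0, 1 - stats::var(bv)))
        } else {
            qtlIdx <- integer(0)
            eff <- numeric(0)
            bv <- rep(0, nOff)
            residSd <- 1
        }
        names(bv) <- offIds

        pen <- factor(sample.int(cfg@nPens, nOff, replace = TRUE),
                      levels = seq_len(cfg@nPens))
        penEff <- stats::rnorm(cfg@nPens, 0, cfg@penEffectSd)
        y <- penEff[as.integer(pen)] + bv + stats::rnorm(nOff, 0, residSd)
        names(pen) <- offIds

        list(genotypes = geno,
             phenotypes = data.frame(sample = offIds, y = y, pen = pen,
                                     stringsAsFactors = FALSE),
             truth = new("TruthSet", breedingValues = bv,
                 qtl = data.frame(index = qtlIdx,
                                  id = markerInfo(geno)$id[qtlIdx],
                                  effect = eff),
                 realizedHeritability = if (stats::var(y) > 0)
                     stats::var(bv) / stats::var(y) else NA_real_,
                 pens = pen),
             founders = founders,
             pedigree = data.frame(id = offIds,
                                   sire = founderIds[sire],
                                   dam = founderIds[cfg@nSires + dam]))
    })
}

#' Residual feed intake from feed intake, metabolic weight and gain
#'
#' RFI is the residual of the least-squares fit
#' ADFI = b0 + b1 * MMBW + b2 * ADG + RFI. Residuals have mean zero and are
#' orthogonal to both regressors; rows with any missing value get NA.
#'
#' @param adfi average daily feed intake
#' @param mmbw mid-test metabolic body weight (MBW^0.75)
#' @param adg average daily gain
#' @return numeric vector of residuals (the derived RFI trait)
#' @export
deriveRfi <- function(adfi, mmbw, adg) {
    stopifnot(length(adfi) == length(mmbw), length(adfi) == length(adg))
    cc <- stats::complete.cases(adfi, mmbw, adg)
    if (sum(cc) < 3) stop("need at least 3 complete cases")
    fit <- stats::lm(adfi ~ mmbw + adg, na.action = stats::na.exclude)
    if (fit$rank < 3)
        stop("regressors are collinear; RFI is not identifiable")
    as.vector(stats::residuals(fit))
}

#' Extract the evenly spaced chip subset of a dense panel
#'
#' Picks \code{ceiling(chipFraction * m)} evenly spaced markers (in sorted
#' panel order), always including both panel ends. The subset is a pure
#' function of the panel size and fraction.
#'
#' @param x GenotypeData at WGS density
#' @param cfg a \linkS4class{SimConfig} (only \code{chipFraction} is used)
#' @return GenotypeData restricted to the chip markers
#' @export
extractChipPanel <- function(x, cfg) {
    stopifnot(is(x, "GenotypeData"), is(cfg, "SimConfig"))
    x[, .chipIndices(nMarkers(x), cfg@chipFraction)]
}

#' Corrupt genotypes by Hardy-Weinberg resampling
#'
#' Emulates imputation error: each non-missing, non-protected genotype is
#' independently replaced with probability \code{errorRate} by a draw from
#' the marker's Hardy-Weinberg genotype distribution (frequencies estimated
#' from the panel). This is a frequency-resampling proxy, not haplotype-aware
#' error.
#'
#' @param x GenotypeData
#' @param errorRate per-genotype replacement probability in [0, 1]
#' @param protected marker indices (columns) never corrupted, e.g. the chip
#'   subset
#' @param seed integer seed
#' @return GenotypeData with corrupted dosages
#' @export
corruptGenotypes <- function(x, errorRate, protected = integer(0), seed = 1L) {
    stopifnot(is(x, "GenotypeData"))
    assertScalar(errorRate, "errorRate", 0, 1)
    if (errorRate == 0) return(x)
    withSeed(seed, {
        d <- dosages(x)
        p <- alleleFrequencies(x)
        hit <- matrix(stats::runif(length(d)) < errorRate,
                      nrow(d), ncol(d))
        if (length(protected)) hit[, protected] <- FALSE
        hit[is.na(d)] <- FALSE
        idx <- which(hit)
        if (length(idx)) {
            pj <- p[(idx - 1) %/% nrow(d) + 1]
            d[idx] <- stats::rbinom(length(idx), 2, pj)
        }
        GenotypeData(d, markerInfo(x))
    })
}

#' Mask whole markers as missing
#'
#' Sets \code{round(fraction * m)} randomly chosen marker columns entirely to
#' missing, returning the mask for later scoring.
#'
#' @param x GenotypeData
#' @param fraction fraction of markers to mask, in (0, 1)
#' @param seed integer seed
#' @return list with \code{genotypes} (masked GenotypeData) and \code{mask}
#'   (sorted integer marker indices)
#' @export
maskGenotypes <- function(x, fraction = 0.02, seed = 1L) {
    stopifnot(is(x, "GenotypeData"))
    assertScalar(fraction, "fraction", 0, 1)
    if (fraction <= 0 || fraction >= 1)
        stop("'fraction' must be strictly between 0 and 1")
    withSeed(seed, {
        m <- nMarkers(x)
        nMask <- max(1L, round(fraction * m))
        mask <- sort(sample.int(m, nMask))
        d <- dosages(x)
        d[, mask] <- NA_real_
        list(genotypes = GenotypeData(d, markerInfo(x)), mask = mask)
    })
}
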