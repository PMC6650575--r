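#' LD pruning specification
#'
#' The window convention follows PLINK's \code{--indep-pairwise} kb mode: a
#' window spans \code{windowSpanBp} base pairs from its anchor marker and the
#' anchor advances by \code{windowStepMarkers} retained markers. Defaults are
#' the 50-kb window / 10-variant step used for dense-panel pruning.
#'
#' @param windowSpanBp window span in bp (> 0)
#' @param windowStepMarkers anchor advance in retained-marker count
#' @param r2Cutoff r-squared threshold in [0, 1]; retained pairs within a
#'   window never exceed it
#' @return a \linkS4class{PruneSpec} object
#' @name PruneSpec-class
#' @exportClass PruneSpec
setClass("PruneSpec", slots = c(windowSpanBp = "numeric",
                                windowStepMarkers = "integer",
                                r2Cutoff = "numeric"))

setValidity("PruneSpec", function(object) {
    if (object@windowSpanBp <= 0) return("windowSpanBp must be > 0")
    if (object@r2Cutoff < 0 || object@r2Cutoff > 1)
        return("r2Cutoff must be in [0, 1]")
    TRUE
})

#' @rdname PruneSpec-class
#' @param windowSpanBp,windowStepMarkers,r2Cutoff see above
#' @export
pruneSpec <- function(windowSpanBp = 5e4, windowStepMarkers = 10L,
                      r2Cutoff = 0.99) {
    new("PruneSpec", windowSpanBp = windowSpanBp,
        windowStepMarkers = as.integer(windowStepMarkers),
        r2Cutoff = r2Cutoff)
}

#' Pairwise LD as squared dosage correlation
#'
#' Squared Pearson correlation of the two dosage vectors over samples
#' non-missing at both markers. NA (flagged undefined) if either marker has
#' zero variance on the intersection.
#'
#' @param x GenotypeData
#' @param i,j marker indices or ids
#' @return r-squared in [0, 1], or NA
#' @export
ldR2 <- function(x, i, j) {
    stopifnot(is(x, "GenotypeData"))
    if (is.character(i)) i <- match(i, markerInfo(x)$id)
    if (is.character(j)) j <- match(j, markerInfo(x)$id)
    a <- dosages(x)[, i]
    b <- dosages(x)[, j]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
        return(NA_real_)
    stats::cor(a[ok], b[ok])^2
}

# pairs (i, j) of indices into `pos` with 0 < pos[j] - pos[i] <= span
.withinSpanPairs <- function(pos, span) {
    n <- length(pos)
    if (n < 2) return(matrix(integer(0), ncol = 2))
    ii <- jj <- integer(0)
    hi <- 1L
    for (i in seq_len(n - 1)) {
        if (hi < i + 1L) hi <- i + 1L
        while (hi < n && pos[hi + 1L] - pos[i] <= span) hi <- hi + 1L
        if (pos[hi] - pos[i] <= span && hi > i) {
            jj <- c(jj, (i + 1L):hi)
            ii <- c(ii, rep.int(i, hi - i))
        }
    }
    cbind(ii, jj)
}

# which member of a violating pair to drop: lower MAF, ties -> later position
.pruneLoser <- function(i, j, maf, pos) {
    if (maf[i] < maf[j]) return(i)
    if (maf[j] < maf[i]) return(j)
    if (pos[i] >= pos[j]) i else j
}

#' Greedy windowed LD pruning
#'
#' Within each chromosome, windows of \code{windowSpanBp} are anchored at
#' retained markers (anchor advancing by \code{windowStepMarkers} retained
#' markers); inside a window the pair with the highest r-squared above the
#' cutoff is repeatedly broken by dropping the lower-MAF member (ties: the
#' later position) until no pair exceeds the cutoff. A final deterministic
#' sweep over all retained within-span pairs enforces the hard guarantee that
#' no two retained markers within \code{windowSpanBp} of each other have
#' r-squared above the cutoff. Windows never cross chromosome boundaries.
#'
#' @param x GenotypeData (markers sorted by chromosome and position)
#' @param spec a \linkS4class{PruneSpec}
#' @return sorted integer indices of retained markers
#' @export
pruneByLd <- function(x, spec = pruneSpec()) {
    stopifnot(is(x, "GenotypeData"), is(spec, "PruneSpec"))
    mk <- markerInfo(x)
    d <- dosages(x)
    p <- alleleFrequencies(x)
    maf <- pmin(p, 1 - p)
    maf[is.nan(maf)] <- 0
    keep <- rep(TRUE, nrow(mk))
    cutoff <- spec@r2Cutoff
    span <- spec@windowSpanBp
    step <- max(1L, spec@windowStepMarkers)

    r2pair <- function(i, j) {
        a <- d[, i]; b <- d[, j]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < 2) return(NA_real_)
        va <- stats::var(a[ok]); vb <- stats::var(b[ok])
        if (va == 0 || vb == 0) return(NA_real_)
        stats::cor(a[ok], b[ok])^2
    }
    pruneWindow <- function(win) {  # win: global indices currently retained
        repeat {
            if (length(win) < 2) return(win)
            r2 <- suppressWarnings(
                stats::cor(d[, win, drop = FALSE],
                           use = "pairwise.complete.obs")^2)
            r2[!upper.tri(r2)] <- NA
            bad <- which(!is.na(r2) & r2 > cutoff, arr.ind = TRUE)
            if (!nrow(bad)) return(win)
            # first violating pair in position order
            at <- bad[order(bad[, 1], bad[, 2])[1], ]
            gi <- win[at[1]]; gj <- win[at[2]]
            loser <- .pruneLoser(gi, gj, maf, mk$pos)
            keep[loser] <<- FALSE
            win <- win[win != loser]
        }
    }

    for (ch in unique(mk$chrom)) {
        chIdx <- which(mk$chrom == ch)
        # anchored pass
        aPtr <- 1L
        repeat {
            ret <- chIdx[keep[chIdx]]
            if (aPtr > length(ret)) break
            a <- ret[aPtr]
            win <- ret[mk$pos[ret] >= mk$pos[a] &
                       mk$pos[ret] <= mk$pos[a] + span]
            pruneWindow(win)
            ret <- chIdx[keep[chIdx]]
            ai <- match(TRUE, ret >= a)
            if (is.na(ai)) break
            aPtr <- ai + step
        }
        # cleanup sweep: enforce the guarantee over all within-span pairs
        repeat {
            ret <- chIdx[keep[chIdx]]
            pairs <- .withinSpanPairs(mk$pos[ret], span)
            if (!nrow(pairs)) break
            r2 <- vapply(seq_len(nrow(pairs)), function(k)
                r2pair(ret[pairs[k, 1]], ret[pairs[k, 2]]), 0.0)
            bad <- which(!is.na(r2) & r2 > cutoff)
            if (!length(bad)) break
            k <- bad[1]   # pairs are generated in position order
            loser <- .pruneLoser(ret[pairs[k, 1]], ret[pairs[k, 2]],
                                 maf, mk$pos)
            keep[loser] <- FALSE
        }
    }
    which(keep)
}

#' Verify the pruning guarantee
#'
#' Exhaustively scans all pairs of retained markers within the window span on
#' the same chromosome; returns TRUE if none exceeds the r-squared cutoff.
#' Violating pairs (if any) are attached as an attribute.
#'
#' @param x GenotypeData
#' @param retained integer marker indices
#' @param spec a \linkS4class{PruneSpec}
#' @return logical, with attribute "violations" (data.frame i, j, r2)
#' @export
verifyPruning <- function(x, retained, spec) {
    mk <- markerInfo(x)
    viol <- data.frame(i = integer(), j = integer(), r2 = numeric())
    for (ch in unique(mk$chrom)) {
        ret <- retained[mk$chrom[retained] == ch]
        pairs <- .withinSpanPairs(mk$pos[ret], spec@windowSpanBp)
        if (!nrow(pairs)) next
        for (k in seq_len(nrow(pairs))) {
            i <- ret[pairs[k, 1]]; j <- ret[pairs[k, 2]]
            r2 <- ldR2(x, i, j)
            if (!is.na(r2) && r2 > spec@r2Cutoff)
                viol <- rbind(viol, data.frame(i = i, j = j, r2 = r2))
        }
    }
    structure(nrow(viol) == 0, violations = viol)
}
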