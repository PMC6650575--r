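#' GWAS-based variant pre-selection specification
#'
#' Seed markers are those with \code{-log10(p)} above the cutoff; the
#' significant region around each seed extends \code{regionHalfwidthBp} on
#' either side of its physical position (overlapping regions are merged).
#' The conventional cutoff grid is 2 to 5; the region half-width is 50 kb.
#'
#' @param negLog10PCutoff \code{-log10(p)} threshold (> 0)
#' @param regionHalfwidthBp half-width of the significant region in bp
#' @return a \linkS4class{SelectionSpec} object
#' @name SelectionSpec-class
#' @exportClass SelectionSpec
setClass("SelectionSpec", slots = c(negLog10PCutoff = "numeric",
                                    regionHalfwidthBp = "numeric"))

setValidity("SelectionSpec", function(object) {
    if (object@negLog10PCutoff <= 0) return("negLog10PCutoff must be > 0")
    if (object@regionHalfwidthBp < 0) return("regionHalfwidthBp must be >= 0")
    TRUE
})

#' @rdname SelectionSpec-class
#' @param negLog10PCutoff,regionHalfwidthBp see above
#' @export
selectionSpec <- function(negLog10PCutoff = 3, regionHalfwidthBp = 5e4) {
    new("SelectionSpec", negLog10PCutoff = negLog10PCutoff,
        regionHalfwidthBp = regionHalfwidthBp)
}

#' Partition a panel into selected and remaining variants around GWAS hits
#'
#' Seeds are testable markers with \code{-log10(p)} above the cutoff. Regions
#' are the per-chromosome union of \code{[pos - hw, pos + hw]} intervals
#' (clipped at 1, overlaps merged via \pkg{IRanges}); the selected set is
#' every panel marker inside any region and the remaining set is the
#' complement, so the result is always a true partition. Seeds always fall in
#' their own region. With no seed markers an empty selected set is returned
#' with a warning.
#'
#' @param gwas GWAS table from \code{runMlma} (coordinates must match the
#'   panel)
#' @param spec a \linkS4class{SelectionSpec}
#' @param x GenotypeData panel to partition
#' @return a \linkS4class{MarkerPartition}
#' @export
selectSignificantRegions <- function(gwas, spec, x) {
    stopifnot(is(spec, "SelectionSpec"), is(x, "GenotypeData"))
    hw <- spec@regionHalfwidthBp
    seeds <- gwas[!is.na(gwas$p) & gwas$negLog10P > spec@negLog10PCutoff, ,
                  drop = FALSE]
    mk <- markerInfo(x)
    if (nrow(seeds) == 0) {
        warning("no markers exceed the -log10(p) cutoff; selected set is empty")
        return(new("MarkerPartition", selected = integer(0),
                   remaining = seq_len(nrow(mk)),
                   regions = data.frame(chrom = character(), start = numeric(),
                                        end = numeric())))
    }
    selected <- integer(0)
    regions <- data.frame(chrom = character(), start = numeric(),
                          end = numeric())
    for (ch in unique(seeds$Chr)) {
        sp <- seeds$bp[seeds$Chr == ch]
        ir <- IRanges::reduce(IRanges::IRanges(start = pmax(1, sp - hw),
                                               end = sp + hw))
        regions <- rbind(regions, data.frame(
            chrom = ch, start = IRanges::start(ir), end = IRanges::end(ir)))
        onCh <- which(mk$chrom == ch)
        if (!length(onCh)) next
        q <- IRanges::IRanges(start = mk$pos[onCh], width = 1)
        hit <- IRanges::overlapsAny(q, ir)
        selected <- c(selected, onCh[hit])
    }
    selected <- sort(selected)
    new("MarkerPartition", selected = selected,
        remaining = setdiff(seq_len(nrow(mk)), selected),
        regions = regions)
}

setMethod("show", "MarkerPartition", function(object) {
    cat("MarkerPartition:", length(object@selected), "selected /",
        length(object@remaining), "remaining markers in",
        nrow(object@regions), "region(s)\n")
})

#' Selected marker indices of a partition
#' @param part a MarkerPartition
#' @export
selectedMarkers <- function(part) part@selected

#' Remaining marker indices of a partition
#' @param part a MarkerPartition
#' @export
remainingMarkers <- function(part) part@remaining

#' Significant regions of a partition
#' @param part a MarkerPartition
#' @return data.frame (chrom, start, end), 1-based closed intervals
#' @export
partitionRegions <- function(part) part@regions

#' Selected-region markers pruned of near-duplicate LD
#'
#' The scheme used for GWAS-pre-selected panels: take the markers inside
#' significant regions, then prune them at r-squared 0.99 so near-perfect
#' duplicates do not dominate the relationship matrix.
#'
#' @param gwas GWAS table
#' @param spec a \linkS4class{SelectionSpec}
#' @param x GenotypeData
#' @param prune a \linkS4class{PruneSpec}; its \code{r2Cutoff} defaults to
#'   0.99
#' @return sorted global marker indices
#' @export
s3MarkerSet <- function(gwas, spec, x, prune = pruneSpec(r2Cutoff = 0.99)) {
    part <- selectSignificantRegions(gwas, spec, x)
    sel <- selectedMarkers(part)
    if (length(sel) < 2) return(sel)
    sel[pruneByLd(x[, sel], prune)]
}

#' Merged prune-and-recombine marker set
#'
#' One side of a selected/remaining partition is pruned at a fixed r-squared
#' (0.1 by default), the other at a varying cutoff, and the two pruned sets
#' are merged. Duplicates are impossible because the partition is disjoint.
#'
#' @param part a \linkS4class{MarkerPartition}
#' @param x GenotypeData the partition refers to
#' @param varying which side gets the varying cutoff: "selected" or
#'   "remaining"
#' @param varyingR2 the varying r-squared cutoff
#' @param fixedR2 the fixed cutoff applied to the other side (default 0.1)
#' @param windowSpanBp,windowStepMarkers window convention for both prunes
#' @return sorted global marker indices of the merged set
#' @export
s4MergedSet <- function(part, x, varying = c("selected", "remaining"),
                        varyingR2, fixedR2 = 0.1,
                        windowSpanBp = 5e4, windowStepMarkers = 10L) {
    varying <- match.arg(varying)
    stopifnot(is(part, "MarkerPartition"), is(x, "GenotypeData"))
    pruneSide <- function(idx, r2) {
        if (length(idx) < 2) return(idx)
        idx[pruneByLd(x[, idx], pruneSpec(windowSpanBp, windowStepMarkers,
                                          r2))]
    }
    selR2 <- if (varying == "selected") varyingR2 else fixedR2
    remR2 <- if (varying == "remaining") varyingR2 else fixedR2
    sort(c(pruneSide(selectedMarkers(part), selR2),
           pruneSide(remainingMarkers(part), remR2)))
}

#' Write a marker set as a one-id-per-line file
#'
#' @param x GenotypeData
#' @param markers integer indices
#' @param path output file
#' @export
writeMarkerSet <- function(x, markers, path) {
    writeLines(markerInfo(x)$id[markers], path)
    invisible(path)
}

#' Write partition regions as a BED file
#'
#' BED is 0-based half-open; internal coordinates are 1-based closed marker
#' positions, so start is shifted by one.
#'
#' @param part a MarkerPartition
#' @param path output file
#' @export
writeRegionsBed <- function(part, path) {
    r <- partitionRegions(part)
    utils::write.table(data.frame(r$chrom, r$start - 1, r$end),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
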