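#' @include AllGenerics.R
NULL

#' Construct a GenotypeData object
#'
#' Markers are sorted by (chromosome, position); dosage columns are reordered
#' to match. Sample identifiers are taken from the rownames of \code{dosages}.
#'
#' @param dosages numeric matrix (samples x markers) with values 0/1/2/NA;
#'   rownames are sample ids. If colnames are absent, marker ids are used.
#' @param markers data.frame with columns id, chrom, pos, a1, a2
#' @return a \linkS4class{GenotypeData} object
#' @examples
#' d <- matrix(c(0, 2, 1, 1), 2, 2, dimnames = list(c("s1", "s2"), NULL))
#' mk <- data.frame(id = c("m1", "m2"), chrom = "1", pos = c(100, 200),
#'                  a1 = "A", a2 = "G")
#' GenotypeData(d, mk)
#' @export
GenotypeData <- function(dosages, markers) {
    dosages <- as.matrix(dosages)
    storage.mode(dosages) <- "double"
    markers <- as.data.frame(markers)
    markers$chrom <- as.character(markers$chrom)
    markers$id <- as.character(markers$id)
    ord <- order(markers$chrom, markers$pos)
    markers <- markers[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
    rownames(markers) <- NULL
    colnames(dosages) <- markers$id
    new("GenotypeData", dosages = dosages, markers = markers)
}

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' @rdname markerInfo
#' @export
setMethod("markerInfo", "GenotypeData", function(x) x@markers)

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "GenotypeData", function(x) rownames(x@dosages))

#' @rdname nMarkers
#' @export
setMethod("nMarkers", "GenotypeData", function(x) ncol(x@dosages))

#' @rdname nSamples
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@dosages))

#' Subset samples and/or markers of a GenotypeData object
#'
#' @param x GenotypeData
#' @param i sample index (integer, logical or character)
#' @param j marker index (integer, logical or character)
#' @param ... ignored
#' @param drop ignored; always FALSE
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
    d <- x@dosages
    mk <- x@markers
    if (!missing(i)) d <- d[i, , drop = FALSE]
    if (!missing(j)) {
        if (is.character(j)) j <- match(j, mk$id)
        d <- d[, j, drop = FALSE]
        mk <- mk[j, , drop = FALSE]
        rownames(mk) <- NULL
    }
    new("GenotypeData", dosages = d, markers = mk)
})

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nrow(object@dosages), "samples x",
        ncol(object@dosages), "markers on",
        length(unique(object@markers$chrom)), "chromosome(s)\n")
    nm <- sum(is.na(object@dosages))
    cat(sprintf("  missing genotypes: %d (%.2f%%)\n", nm,
                100 * nm / length(object@dosages)))
})

#' Counted-allele frequencies from non-missing calls
#'
#' @param x GenotypeData
#' @return numeric vector of per-marker A1/ALT allele frequencies (NaN for
#'   markers with no calls)
#' @export
alleleFrequencies <- function(x) {
    stopifnot(is(x, "GenotypeData"))
    colMeans(x@dosages, na.rm = TRUE) / 2
}

#' Per-marker and per-sample call rates
#'
#' @param x GenotypeData
#' @return list with elements \code{marker} and \code{sample}
#' @export
callRates <- function(x) {
    stopifnot(is(x, "GenotypeData"))
    ok <- !is.na(x@dosages)
    list(marker = colMeans(ok), sample = rowMeans(ok))
}
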