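#' Genomic relationship matrix (VanRaden method 1)
#'
#' \code{G = M M' / (2 * sum p_i (1 - p_i))} where M is the dosage matrix with
#' \code{2 p_i} subtracted from each column and \code{p_i} is the observed
#' counted-allele frequency from non-missing calls. Missing dosages are
#' replaced by the column mean (zero after centering), which preserves
#' \code{E[M] = 0}. Monomorphic markers are dropped from both numerator and
#' denominator.
#'
#' @param x GenotypeData
#' @param markers optional marker subset (integer/logical index or marker ids)
#' @return a \linkS4class{GRM} object
#' @examples
#' g <- GenotypeData(matrix(c(0, 2, 2, 0), 2, 2,
#'                          dimnames = list(c("s1", "s2"), NULL)),
#'                   data.frame(id = c("m1", "m2"), chrom = "1",
#'                              pos = c(1, 2), a1 = "A", a2 = "G"))
#' grmValues(computeGrm(g))  # [[2, -2], [-2, 2]]
#' @export
computeGrm <- function(x, markers = NULL) {
    stopifnot(is(x, "GenotypeData"))
    if (!is.null(markers)) {
        if (is.character(markers)) {
            bad <- setdiff(markers, markerInfo(x)$id)
            if (length(bad))
                stop("unknown marker ids: ", paste(utils::head(bad, 5),
                                                   collapse = ", "))
        } else if (is.numeric(markers) &&
                   (any(markers < 1) || any(markers > nMarkers(x)))) {
            stop("marker subset indices out of range")
        }
        x <- x[, markers]
    }
    d <- dosages(x)
    p <- colMeans(d, na.rm = TRUE) / 2
    poly <- !is.nan(p) & p > 0 & p < 1
    if (!any(poly))
        stop("no polymorphic markers: cannot build a relationship matrix")
    d <- d[, poly, drop = FALSE]
    p <- p[poly]
    M <- sweep(d, 2, 2 * p)
    M[is.na(M)] <- 0
    sc <- 2 * sum(p * (1 - p))
    G <- tcrossprod(M) / sc
    new("GRM", values = G, scale = sc, nMarkersUsed = sum(poly),
        frequencies = p)
}

#' @rdname grmValues
#' @export
setMethod("grmValues", "GRM", function(x) x@values)

#' @rdname grmScale
#' @export
setMethod("grmScale", "GRM", function(x) x@scale)

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "GRM", function(x) rownames(x@values))

#' @rdname nSamples
#' @export
setMethod("nSamples", "GRM", function(x) nrow(x@values))

setMethod("show", "GRM", function(object) {
    cat("GRM:", nrow(object@values), "samples,",
        object@nMarkersUsed, "markers used\n")
    cat(sprintf("  scale 2*sum(p(1-p)) = %.4f; mean diagonal = %.4f\n",
                object@scale, mean(diag(object@values))))
})

#' Subset a GRM to a set of samples
#'
#' @param x GRM
#' @param i sample index (integer, logical or character)
#' @param j same as i (must match if given)
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "GRM", function(x, i, j, ..., drop = FALSE) {
    if (missing(j)) j <- i
    new("GRM", values = x@values[i, j, drop = FALSE], scale = x@scale,
        nMarkersUsed = x@nMarkersUsed, frequencies = x@frequencies)
})

#' Write a GRM in the GCTA binary convention
#'
#' Writes \code{<prefix>.grm.bin} (float32 lower triangle including the
#' diagonal, row by row), \code{<prefix>.grm.N.bin} (float32 marker counts)
#' and \code{<prefix>.grm.id} (tab-delimited FID/IID).
#'
#' @param grm a GRM object
#' @param pathPrefix output path prefix
#' @export
writeGrm <- function(grm, pathPrefix) {
    stopifnot(is(grm, "GRM"))
    n <- nSamples(grm)
    v <- grm@values
    lower <- unlist(lapply(seq_len(n), function(i) v[i, seq_len(i)]))
    writeBin(as.numeric(lower), paste0(pathPrefix, ".grm.bin"), size = 4)
    writeBin(rep(as.numeric(grm@nMarkersUsed), length(lower)),
             paste0(pathPrefix, ".grm.N.bin"), size = 4)
    ids <- sampleIDs(grm)
    utils::write.table(data.frame(ids, ids), paste0(pathPrefix, ".grm.id"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(pathPrefix)
}

#' Read a GRM written in the GCTA binary convention
#'
#' @param pathPrefix path prefix used by \code{writeGrm}
#' @return a GRM object (scale is not stored in the format and is set to the
#'   marker count as a nominal positive value)
#' @export
readGrm <- function(pathPrefix) {
    ids <- utils::read.table(paste0(pathPrefix, ".grm.id"),
                             colClasses = "character")[[2]]
    n <- length(ids)
    nv <- n * (n + 1) / 2
    lower <- readBin(paste0(pathPrefix, ".grm.bin"), "numeric",
                     n = nv, size = 4)
    nm <- readBin(paste0(pathPrefix, ".grm.N.bin"), "numeric",
                  n = 1, size = 4)
    v <- matrix(0, n, n, dimnames = list(ids, ids))
    k <- 1
    for (i in seq_len(n)) {
        v[i, seq_len(i)] <- lower[k:(k + i - 1)]
        k <- k + i
    }
    v[upper.tri(v)] <- t(v)[upper.tri(v)]
    new("GRM", values = v, scale = max(nm, 1), nMarkersUsed = as.integer(nm),
        frequencies = numeric(0))
}

#' Write a GRM as a plain delimited matrix
#'
#' @param grm a GRM object
#' @param path output file (tab-delimited, with sample ids as header and
#'   first column)
#' @export
writeGrmText <- function(grm, path) {
    utils::write.table(grm@values, path, sep = "\t", quote = FALSE,
                       col.names = NA)
    invisible(path)
}
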