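## Readers/writers for PLINK (.bed/.bim/.fam binary, .ped/.map text) and VCF.
## Dosages always count the A1 (PLINK) / ALT (VCF) allele.

# 2-bit PLINK codes -> dosage of A1: 00 hom A1 = 2, 01 missing, 10 het, 11 hom A2
.bedCodeToDosage <- c(2, NA, 1, 0)
.dosageToBedCode <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])

#' Read PLINK genotype files
#'
#' Reads a \code{.bed/.bim/.fam} triple (SNP-major PLINK 1 binary) or, if no
#' \code{.bed} is present, a \code{.ped/.map} text pair. For binary input the
#' counted allele is A1 from the \code{.bim}; for text input, where no A1 is
#' declared, the minor allele is counted (ties broken by sort order).
#'
#' @param pathPrefix path without extension
#' @return a \linkS4class{GenotypeData} object, marker order as in the file
#' @export
readPlink <- function(pathPrefix) {
    bed <- paste0(pathPrefix, ".bed")
    if (file.exists(bed)) .readBed(pathPrefix) else .readPedMap(pathPrefix)
}

.readBed <- function(pathPrefix) {
    bed <- paste0(pathPrefix, ".bed")
    bim <- utils::read.table(paste0(pathPrefix, ".bim"),
        col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
        colClasses = c("character", "character", "numeric", "integer",
                       "character", "character"))
    fam <- utils::read.table(paste0(pathPrefix, ".fam"),
        colClasses = "character")
    n <- nrow(fam); m <- nrow(bim)
    raw <- readBin(bed, "raw", n = file.size(bed))
    if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
        stop(sprintf("'%s': bad magic bytes at offset 0 (not a PLINK .bed file)",
                     bed))
    if (raw[3] != as.raw(0x01))
        stop(sprintf("'%s': unsupported mode byte 0x%02x at offset 2 (need SNP-major 0x01)",
                     bed, as.integer(raw[3])))
    bps <- ceiling(n / 4)
    if (length(raw) - 3L != bps * m)
        stop(sprintf(
            "'%s': expected %d data bytes for %d samples x %d markers, found %d at offset 3",
            bed, bps * m, n, m, length(raw) - 3L))
    b <- matrix(as.integer(raw[-(1:3)]), nrow = bps, ncol = m)
    codes <- matrix(0L, nrow = 4L * bps, ncol = m)
    for (k in 0:3)
        codes[seq.int(k + 1L, 4L * bps, by = 4L), ] <- (b %/% 4L^k) %% 4L
    d <- matrix(.bedCodeToDosage[codes[seq_len(n), , drop = FALSE] + 1L],
                nrow = n, ncol = m)
    rownames(d) <- fam[[2]]
    GenotypeData(d, bim[, c("id", "chrom", "pos", "a1", "a2")])
}

.readPedMap <- function(pathPrefix) {
    map <- utils::read.table(paste0(pathPrefix, ".map"),
        col.names = c("chrom", "id", "cm", "pos"),
        colClasses = c("character", "character", "numeric", "integer"))
    ped <- utils::read.table(paste0(pathPrefix, ".ped"),
        colClasses = "character")
    m <- nrow(map)
    if (ncol(ped) != 6 + 2 * m)
        stop(sprintf(".ped has %d columns; expected %d for %d markers",
                     ncol(ped), 6 + 2 * m, m))
    ids <- ped[[2]]
    a <- as.matrix(ped[, 6 + seq_len(2 * m), drop = FALSE])
    a[a == "0"] <- NA
    d <- matrix(NA_real_, nrow(ped), m)
    a1 <- a2 <- character(m)
    for (j in seq_len(m)) {
        al <- a[, c(2 * j - 1, 2 * j), drop = FALSE]
        lv <- sort(unique(al[!is.na(al)]))
        if (length(lv) == 0) lv <- c("0", "0")
        cnt <- vapply(lv, function(x) sum(al == x, na.rm = TRUE), 0L)
        minor <- lv[which.min(cnt)]   # ties: first in sort order
        a1[j] <- minor
        a2[j] <- if (length(lv) > 1) lv[lv != minor][1] else minor
        d[, j] <- rowSums(al == minor)
    }
    rownames(d) <- ids
    GenotypeData(d, data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                               a1 = a1, a2 = a2))
}

#' Write PLINK .bed/.bim/.fam files
#'
#' SNP-major PLINK 1 binary; dosage 2 is written as homozygous A1.
#'
#' @param x GenotypeData
#' @param pathPrefix output path without extension
#' @return invisibly, the path prefix
#' @export
writePlink <- function(x, pathPrefix) {
    stopifnot(is(x, "GenotypeData"))
    mk <- markerInfo(x)
    utils::write.table(
        data.frame(mk$chrom, mk$id, 0, mk$pos, mk$a1, mk$a2),
        paste0(pathPrefix, ".bim"),
        quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
    ids <- sampleIDs(x)
    utils::write.table(
        data.frame(ids, ids, 0, 0, 0, -9),
        paste0(pathPrefix, ".fam"),
        quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
    d <- dosages(x)
    n <- nrow(d); m <- ncol(d)
    bps <- ceiling(n / 4)
    out <- raw(3 + bps * m)
    out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
    codes <- matrix(0L, 4L * bps, m)
    codes[seq_len(n), ] <- .dosageToBedCode(d)
    bytes <- codes[seq.int(1, 4 * bps, 4), , drop = FALSE] +
        4L * codes[seq.int(2, 4 * bps, 4), , drop = FALSE] +
        16L * codes[seq.int(3, 4 * bps, 4), , drop = FALSE] +
        64L * codes[seq.int(4, 4 * bps, 4), , drop = FALSE]
    out[-(1:3)] <- as.raw(bytes)
    writeBin(out, paste0(pathPrefix, ".bed"))
    invisible(pathPrefix)
}

#' Read genotypes from a VCF file
#'
#' Uses \pkg{vcfR} for parsing. Dosage is the ALT-allele count of the diploid
#' GT field; half calls and missing GTs become NA. Multi-allelic records are
#' either an error or dropped, per \code{multiallelic}.
#'
#' @param path VCF file (optionally bgzipped)
#' @param multiallelic "error" (default) or "drop"
#' @return a \linkS4class{GenotypeData} object
#' @export
readVcfGeno <- function(path, multiallelic = c("error", "drop")) {
    multiallelic <- match.arg(multiallelic)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi)) {
        if (multiallelic == "error")
            stop(sprintf("multi-allelic record(s) at %s",
                         paste(paste0(fix$CHROM[multi], ":", fix$POS[multi]),
                               collapse = ", ")))
        v <- v[!multi, ]
        fix <- fix[!multi, , drop = FALSE]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    samples <- colnames(gt)
    m <- nrow(gt)
    d <- matrix(NA_real_, length(samples), m)
    for (j in seq_len(m)) {
        parts <- strsplit(gt[j, ], "[/|]")
        nall <- lengths(parts)
        nall[is.na(gt[j, ])] <- 2L   # fully missing call is fine
        if (any(nall != 2))
            stop(sprintf("non-diploid GT in record %d (%s)", j,
                         if (!is.na(fix$ID[j])) fix$ID[j]
                         else paste0(fix$CHROM[j], ":", fix$POS[j])))
        d[, j] <- vapply(parts, function(al) {
            if (length(al) != 2 || any(al == ".") || any(is.na(al)))
                return(NA_real_)
            if (!all(al %in% c("0", "1")))
                stop("unexpected allele index in GT field")
            sum(al == "1")
        }, 0.0)
    }
    rownames(d) <- samples
    ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                  paste0(fix$CHROM, "_", fix$POS), fix$ID)
    GenotypeData(d, data.frame(id = ids, chrom = fix$CHROM,
                               pos = as.integer(fix$POS),
                               a1 = fix$ALT, a2 = fix$REF))
}

#' Write genotypes as a minimal VCF v4.2 file
#'
#' The counted allele (a1) is written as ALT and a2 as REF, so that
#' \code{readVcfGeno} round-trips dosages.
#'
#' @param x GenotypeData
#' @param path output file
#' @return invisibly, the path
#' @export
writeVcfGeno <- function(x, path) {
    stopifnot(is(x, "GenotypeData"))
    mk <- markerInfo(x)
    d <- dosages(x)
    gtStr <- c("0/0", "0/1", "1/1")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", sampleIDs(x)), collapse = "\t")),
               con)
    for (j in seq_len(nrow(mk))) {
        g <- ifelse(is.na(d[, j]), "./.", gtStr[d[, j] + 1])
        writeLines(paste(c(mk$chrom[j], mk$pos[j], mk$id[j], mk$a2[j],
                           mk$a1[j], ".", "PASS", ".", "GT", g),
                         collapse = "\t"), con)
    }
    invisible(path)
}

#' Read a phenotype / fixed-effect table
#'
#' Tab-delimited with a header; the first column is the sample identifier.
#'
#' @param path file path
#' @return data.frame; first column named as in the file, one row per sample
#' @export
readPhenotypes <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    df[[1]] <- as.character(df[[1]])
    if (anyDuplicated(df[[1]]))
        stop("duplicate sample identifiers in phenotype table")
    df
}

#' Write a phenotype / fixed-effect table
#'
#' @param df data.frame, first column sample identifiers
#' @param path output file
#' @export
writePhenotypes <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
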