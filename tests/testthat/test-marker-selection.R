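# dense map: 200 markers across 2 Mb (avg 10 kb gap) so 50-kb windows hold
# several markers
denseLdGeno <- function(seed = 1, m = 200, n = 120, rho = 0.9) {
    cfg <- simConfig(nSires = 15, nDams = n / 2, offspringPerDam = 2,
                     nChromosomes = 1, markersPerChromosome = m,
                     chromosomeLengthBp = 2e6, founderLdDecay = rho,
                     nQtl = 1, seed = seed)
    simulatePopulation(cfg)$genotypes
}

test_that("pairwise LD is a squared dosage correlation with sign invariance", {
    g <- randomGeno(20, 6, seed = 2)
    d <- dosages(g)
    d[, 2] <- d[, 1]          # identical column
    d[, 3] <- 2 - d[, 1]      # flipped allele coding
    d[, 4] <- 1               # constant
    d[1:3, 5] <- NA
    g <- makeGeno(d)
    expect_equal(ldR2(g, 1, 2), 1.0, tolerance = 1e-12)
    expect_equal(ldR2(g, 1, 3), 1.0, tolerance = 1e-12)
    expect_true(is.na(ldR2(g, 1, 4)))
    # brute-force two-pass formula on the pairwise-complete subset
    ok <- !is.na(d[, 5]) & !is.na(d[, 6])
    a <- d[ok, 5]; b <- d[ok, 6]
    r2 <- (mean(a * b) - mean(a) * mean(b))^2 /
        (mean(a^2) - mean(a)^2) / (mean(b^2) - mean(b)^2)
    expect_equal(ldR2(g, 5, 6), r2, tolerance = 1e-10)
})

test_that("identical adjacent markers collapse to a single representative", {
    base <- rbinom(50, 2, 0.5)
    d <- cbind(base, base, base, rbinom(50, 2, 0.4))
    rownames(d) <- sprintf("s%02d", 1:50)
    g <- makeGeno(d, pos = c(1000, 2000, 3000, 4000))
    kept <- pruneByLd(g, pruneSpec(5e4, 10, 0.99))
    expect_length(intersect(kept, 1:3), 1L)
    expect_true(4 %in% kept)
})

test_that("a cutoff of 1 with no perfect pairs is the identity", {
    g <- denseLdGeno(seed = 3)
    r2max <- max(sapply(seq_len(nMarkers(g) - 1),
                        function(j) ldR2(g, j, j + 1)), na.rm = TRUE)
    if (r2max < 1) {
        kept <- pruneByLd(g, pruneSpec(5e4, 10, 1.0))
        expect_identical(kept, seq_len(nMarkers(g)))
    }
    expect_true(TRUE)
})

test_that("pruning satisfies its guarantee and tracks a reference greedy", {
    g <- denseLdGeno(seed = 4)
    spec <- pruneSpec(5e4, 10, 0.2)
    kept <- pruneByLd(g, spec)
    expect_true(verifyPruning(g, kept, spec))
    ref <- oracleGreedyPrune(g, 5e4, 0.2)
    expect_lt(abs(length(kept) - length(ref)) / length(ref), 0.10)
})

test_that("retained count is monotone non-decreasing in the r2 cutoff", {
    g <- denseLdGeno(seed = 5)
    cutoffs <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.99)
    counts <- sapply(cutoffs, function(cz)
        length(pruneByLd(g, pruneSpec(5e4, 10, cz))))
    expect_true(all(diff(counts) >= 0))
})

test_that("significant regions are the merged 50-kb flanks of seed markers", {
    pos <- c(40000, 60000, 100000, 149000, 151000, 160000, 260000, 400000)
    d <- sapply(seq_along(pos), function(i) rbinom(30, 2, 0.5))
    rownames(d) <- sprintf("s%02d", 1:30)
    g <- makeGeno(d, pos = pos)
    gwas <- data.frame(Chr = "1", SNP = markerInfo(g)$id, bp = pos,
                       p = 1, negLog10P = 0, tested = TRUE)
    gwas$p[3] <- 1e-4; gwas$negLog10P[3] <- 4      # seed at 100 kb
    part <- selectSignificantRegions(gwas, selectionSpec(3), g)
    expect_equal(partitionRegions(part),
                 data.frame(chrom = "1", start = 50000, end = 150000))
    expect_equal(selectedMarkers(part), c(2, 3, 4))  # 60k, 100k, 149k
    # a second seed at 160 kb merges into one region [50k, 210k]
    gwas$p[6] <- 1e-4; gwas$negLog10P[6] <- 4
    part2 <- selectSignificantRegions(gwas, selectionSpec(3), g)
    expect_equal(partitionRegions(part2),
                 data.frame(chrom = "1", start = 50000, end = 210000))
    expect_equal(selectedMarkers(part2), 2:6)
    expect_equal(remainingMarkers(part2), c(1, 7, 8))
})

test_that("every partition is disjoint and exhaustive", {
    st <- smallStudy(seed = 6)
    gw <- runMlma(st$y, st$X, extractChipPanel(st$sim$genotypes, st$cfg),
                  st$sim$genotypes)
    for (cutoff in c(1, 2, 3)) {
        part <- selectSignificantRegions(gw, selectionSpec(cutoff),
                                         st$sim$genotypes)
        expect_length(intersect(selectedMarkers(part),
                                remainingMarkers(part)), 0L)
        expect_setequal(c(selectedMarkers(part), remainingMarkers(part)),
                        seq_len(nMarkers(st$sim$genotypes)))
    }
    expect_warning(
        selectSignificantRegions(gw, selectionSpec(50), st$sim$genotypes),
        "empty")
})

test_that("the selected-then-pruned set composes its two steps", {
    g <- denseLdGeno(seed = 7)
    set.seed(8)
    y <- setNames(rnorm(nSamples(g)), sampleIDs(g))
    gw <- runMlma(y, NULL, computeGrm(g), g)
    spec <- selectionSpec(quantile(gw$negLog10P, 0.8, na.rm = TRUE))
    stepwise <- {
        part <- selectSignificantRegions(gw, spec, g)
        sel <- selectedMarkers(part)
        sel[pruneByLd(g[, sel], pruneSpec(r2Cutoff = 0.99))]
    }
    expect_identical(s3MarkerSet(gw, spec, g), stepwise)
    # a duplicated marker inside a region keeps one copy
    dup <- cbind(dosages(g)[, 1:20], dosages(g)[, 10])
    gdup <- makeGeno(dup, pos = c(markerInfo(g)$pos[1:20],
                                  markerInfo(g)$pos[10] + 1L))
    gw2 <- data.frame(Chr = "1", SNP = markerInfo(gdup)$id,
                      bp = markerInfo(gdup)$pos, p = 1, negLog10P = 0,
                      tested = TRUE)
    seedRow <- which(markerInfo(gdup)$pos == markerInfo(g)$pos[10])
    gw2$p[seedRow] <- 1e-5; gw2$negLog10P[seedRow] <- 5
    s3 <- s3MarkerSet(gw2, selectionSpec(3), gdup)
    dupPair <- which(markerInfo(gdup)$pos %in%
                     c(markerInfo(g)$pos[10], markerInfo(g)$pos[10] + 1L))
    expect_length(intersect(s3, dupPair), 1L)
})

test_that("merged prune-and-recombine sets behave as specified", {
    g <- denseLdGeno(seed = 9)
    set.seed(10)
    y <- setNames(rnorm(nSamples(g)), sampleIDs(g))
    gw <- runMlma(y, NULL, computeGrm(g), g)
    spec <- selectionSpec(quantile(gw$negLog10P, 0.85, na.rm = TRUE))
    part <- selectSignificantRegions(gw, spec, g)
    # symmetric when both cutoffs coincide
    a <- s4MergedSet(part, g, "selected", varyingR2 = 0.1, fixedR2 = 0.1)
    b <- s4MergedSet(part, g, "remaining", varyingR2 = 0.1, fixedR2 = 0.1)
    expect_identical(a, b)
    # varying side passes through unpruned at cutoff 1 when no perfect pairs
    sel <- selectedMarkers(part)
    selR2 <- if (length(sel) > 1) {
        pr <- suppressWarnings(
            cor(dosages(g)[, sel], use = "pairwise.complete.obs")^2)
        max(pr[upper.tri(pr)], na.rm = TRUE)
    } else 0
    if (selR2 < 1) {
        full <- s4MergedSet(part, g, "selected", varyingR2 = 1.0)
        expect_true(all(sel %in% full))
    }
    # merged-set size is non-decreasing in the varying cutoff, both ways
    cutoffs <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.99)
    for (side in c("selected", "remaining")) {
        sizes <- sapply(cutoffs, function(cz)
            length(s4MergedSet(part, g, side, varyingR2 = cz)))
        expect_true(all(diff(sizes) >= 0))
    }
})
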