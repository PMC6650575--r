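test_that("the simulator is deterministic under a fixed seed", {
    cfg <- simConfig(nSires = 4, nDams = 12, offspringPerDam = 2,
                     nChromosomes = 2, markersPerChromosome = 40, nQtl = 5,
                     seed = 77)
    a <- simulatePopulation(cfg)
    b <- simulatePopulation(cfg)
    expect_identical(dosages(a$genotypes), dosages(b$genotypes))
    expect_identical(a$phenotypes$y, b$phenotypes$y)
    expect_identical(a$truth@qtl, b$truth@qtl)
})

test_that("every offspring genotype is Mendelian-consistent with its parents", {
    st <- smallStudy(seed = 5)
    ped <- st$sim$pedigree
    dOff <- dosages(st$sim$genotypes)
    dPar <- dosages(st$sim$founders)
    # transmitted allele count per parent: dosage 0 -> 0, 1 -> {0,1}, 2 -> 1
    lo <- function(d) (d == 2) * 1
    hi <- function(d) (d >= 1) * 1
    minO <- lo(dPar[ped$sire, ]) + lo(dPar[ped$dam, ])
    maxO <- hi(dPar[ped$sire, ]) + hi(dPar[ped$dam, ])
    expect_true(all(dOff >= minO & dOff <= maxO))
})

test_that("adjacent-marker LD in founders increases with the decay parameter", {
    rhos <- seq(0.1, 0.9, by = 0.1)
    meanR2 <- sapply(rhos, function(rho) {
        cfg <- simConfig(nSires = 40, nDams = 40, offspringPerDam = 1,
                         nChromosomes = 1, markersPerChromosome = 80,
                         founderLdDecay = rho, nQtl = 1, seed = 11)
        sim <- simulatePopulation(cfg)
        d <- dosages(sim$founders)
        r2 <- sapply(seq_len(ncol(d) - 1), function(j)
            suppressWarnings(cor(d[, j], d[, j + 1])^2))
        mean(r2, na.rm = TRUE)
    })
    expect_gt(cor(rhos, meanR2, method = "spearman"), 0.9)
})

test_that("within-pen heritability is realized near its target", {
    ratios <- sapply(1:20, function(s) {
        cfg <- simConfig(nSires = 15, nDams = 100, offspringPerDam = 3,
                         nChromosomes = 1, markersPerChromosome = 60,
                         nQtl = 20, heritability = 0.3, seed = 1000 + s)
        sim <- simulatePopulation(cfg)
        bv <- sim$truth@breedingValues
        y <- sim$phenotypes$y
        pen <- sim$phenotypes$pen
        var(bv - ave(bv, pen)) / var(y - ave(y, pen))
    })
    expect_gt(mean(ratios), 0.25)
    expect_lt(mean(ratios), 0.35)
})

test_that("a zero-QTL trait is pen plus noise with no genetic signal", {
    cfg <- simConfig(nSires = 5, nDams = 20, offspringPerDam = 3,
                     nChromosomes = 1, markersPerChromosome = 30, nQtl = 0,
                     seed = 2)
    sim <- simulatePopulation(cfg)
    expect_true(all(sim$truth@breedingValues == 0))
    expect_equal(sim$truth@realizedHeritability, 0)
})

test_that("RFI is the least-squares residual of feed intake", {
    # exact plane: residuals identically zero
    mmbw <- c(5.1, 5.6, 5.3, 6.2, 5.9, 6.0)
    adg <- c(1.0, 1.2, 0.9, 1.3, 1.1, 1.05)
    adfi <- 2 + 1.5 * mmbw + 3 * adg
    expect_equal(deriveRfi(adfi, mmbw, adg), rep(0, 6), tolerance = 1e-10)
    # noise recovery and orthogonality
    set.seed(10)
    mmbw <- rnorm(200, 6, 0.5); adg <- rnorm(200, 1, 0.1)
    eps <- rnorm(200)
    rfi <- deriveRfi(mmbw + eps, mmbw, adg)
    expect_equal(mean(rfi), 0, tolerance = 1e-10)
    expect_equal(cor(rfi, mmbw), 0, tolerance = 1e-10)
    expect_equal(cor(rfi, adg), 0, tolerance = 1e-10)
    expect_gt(cor(rfi, eps), 0.95)
    # 5-row hand table vs the normal-equations oracle
    adfi5 <- c(10, 12, 11, 14, 13)
    mmbw5 <- c(5.0, 5.5, 5.2, 6.0, 5.8)
    adg5 <- c(1.0, 1.2, 0.9, 1.3, 1.1)
    A <- cbind(1, mmbw5, adg5)
    bhat <- solve(t(A) %*% A) %*% t(A) %*% adfi5
    expect_equal(deriveRfi(adfi5, mmbw5, adg5),
                 as.vector(adfi5 - A %*% bhat), tolerance = 1e-10)
    # collinear regressors are rejected
    expect_error(deriveRfi(adfi5, mmbw5, 2 * mmbw5), "collinear")
})

test_that("the chip panel is an evenly spaced subset spanning the map", {
    g <- randomGeno(10, 1000, seed = 6)
    cfg <- simConfig(chipFraction = 0.1)
    chip <- extractChipPanel(g, cfg)
    expect_equal(nMarkers(chip), 100L)
    expect_true(all(markerInfo(chip)$id %in% markerInfo(g)$id))
    pos <- markerInfo(g)$pos
    gap <- max(diff(pos))
    expect_lte(markerInfo(chip)$pos[1] - pos[1], gap)
    expect_lte(pos[1000] - markerInfo(chip)$pos[100], gap)
    # identity at fraction 1
    expect_identical(dosages(extractChipPanel(g, simConfig(chipFraction = 1))),
                     dosages(g))
})

test_that("genotype corruption matches its binomial error model", {
    expect_identical(dosages(corruptGenotypes(randomGeno(20, 50), 0)),
                     dosages(randomGeno(20, 50)))
    # degenerate frequency: every corrupted call drawn as hom for the fixed allele
    d <- matrix(2, 40, 5, dimnames = list(sprintf("s%02d", 1:40), NULL))
    d[1, 1] <- 2  # p = 1 at all markers
    gFix <- makeGeno(d)
    expect_true(all(dosages(corruptGenotypes(gFix, 1, seed = 3)) == 2))
    # observed change fraction within the binomial 99% CI
    g <- randomGeno(500, 200, seed = 7)
    gc <- corruptGenotypes(g, 0.1, seed = 8)
    p <- alleleFrequencies(g)
    # P(draw differs | hit) at each marker, genotype-frequency weighted
    pd <- sapply(seq_along(p), function(j) {
        gf <- c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2)
        tab <- tabulate(dosages(g)[, j] + 1, 3) / 500
        sum(tab * (1 - gf))
    })
    expChange <- 0.1 * mean(pd)
    nCells <- 500 * 200
    obs <- mean(dosages(gc) != dosages(g))
    ci <- 2.576 * sqrt(expChange * (1 - expChange) / nCells)
    expect_lt(abs(obs - expChange), ci + 1e-4)
    # protected markers untouched
    gp <- corruptGenotypes(g, 0.5, protected = 1:50, seed = 9)
    expect_identical(dosages(gp)[, 1:50], dosages(g)[, 1:50])
})

test_that("masking hides whole markers and is reproducible", {
    g <- randomGeno(30, 500, seed = 12)
    mk <- maskGenotypes(g, 0.02, seed = 4)
    expect_length(mk$mask, 10L)              # 2% of 500
    expect_true(all(is.na(dosages(mk$genotypes)[, mk$mask])))
    keep <- setdiff(seq_len(500), mk$mask)
    expect_identical(dosages(mk$genotypes)[, keep], dosages(g)[, keep])
    mk2 <- maskGenotypes(g, 0.02, seed = 4)
    expect_identical(mk$mask, mk2$mask)
})

test_that("phenotype regresses on true breeding value with unit slope", {
    slopes <- sapply(1:20, function(s) {
        cfg <- simConfig(nSires = 20, nDams = 120, offspringPerDam = 2,
                         nChromosomes = 1, markersPerChromosome = 80,
                         nQtl = 25, heritability = 0.4, seed = 3000 + s)
        sim <- simulatePopulation(cfg)
        bv <- sim$truth@breedingValues
        y <- sim$phenotypes$y
        pen <- sim$phenotypes$pen
        coef(lm((y - ave(y, pen)) ~ I(bv - ave(bv, pen))))[2]
    })
    expect_lt(abs(mean(slopes) - 1), 0.1)
})
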