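# Small in-code fixtures used across tests.

# GenotypeData from a bare dosage matrix; markers laid out on one chromosome
# (or as given), default inter-marker gap 1 kb.
makeGeno <- function(d, chrom = "1", pos = NULL, a1 = "A", a2 = "G") {
    d <- as.matrix(d)
    if (is.null(rownames(d))) rownames(d) <- sprintf("s%03d", seq_len(nrow(d)))
    m <- ncol(d)
    if (is.null(pos)) pos <- seq_len(m) * 1000L
    GenotypeData(d, data.frame(id = sprintf("m%04d", seq_len(m)),
                               chrom = rep_len(chrom, m), pos = pos,
                               a1 = rep_len(a1, m), a2 = rep_len(a2, m)))
}

# Random polymorphic panel under HWE (no LD, no structure)
randomGeno <- function(n, m, seed = 1) {
    set.seed(seed)
    p <- runif(m, 0.1, 0.9)
    d <- sapply(p, function(pp) rbinom(n, 2, pp))
    makeGeno(d)
}

# fresh scratch directory for file-format round-trips
withr_like_tempdir <- function() {
    d <- tempfile("wgsblup-test-")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
}

# A small simulated study shared by several tests
smallStudy <- function(seed = 42, ...) {
    cfg <- simConfig(nSires = 10, nDams = 60, offspringPerDam = 3,
                     nChromosomes = 2, markersPerChromosome = 100,
                     nQtl = 20, heritability = 0.4, seed = seed, ...)
    sim <- simulatePopulation(cfg)
    list(cfg = cfg, sim = sim,
         y = setNames(sim$phenotypes$y, sim$phenotypes$sample),
         X = stats::model.matrix(~ pen, sim$phenotypes))
}
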