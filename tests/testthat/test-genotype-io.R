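test_that("PLINK binary round-trips bit-identically, including missing codes", {
    g <- makeGeno(matrix(c(0, 2, 1, NA, 2, 0, 1, 1, NA, 0), nrow = 2),
                  chrom = c("1", "1", "1", "2", "2"))
    pre <- file.path(withr_like_tempdir(), "panel")
    writePlink(g, pre)
    g2 <- readPlink(pre)
    expect_identical(dosages(g2), dosages(g))
    expect_identical(markerInfo(g2)$pos, markerInfo(g)$pos)
    # byte-identical on rewrite
    pre2 <- file.path(dirname(pre), "panel2")
    writePlink(g2, pre2)
    expect_identical(readBin(paste0(pre, ".bed"), "raw", 1000),
                     readBin(paste0(pre2, ".bed"), "raw", 1000))
})

test_that("bed magic and dimension checks reject malformed files", {
    g <- makeGeno(matrix(c(0, 1, 2, 1), 2, 2))
    pre <- file.path(withr_like_tempdir(), "bad")
    writePlink(g, pre)
    raw <- readBin(paste0(pre, ".bed"), "raw", file.size(paste0(pre, ".bed")))
    raw[3] <- as.raw(0x00)                       # sample-major mode
    writeBin(raw, paste0(pre, ".bed"))
    expect_error(readPlink(pre), "offset 2")
    raw[1] <- as.raw(0x00); raw[3] <- as.raw(0x01)
    writeBin(raw, paste0(pre, ".bed"))
    expect_error(readPlink(pre), "magic")
    writePlink(g, pre)
    raw <- readBin(paste0(pre, ".bed"), "raw", file.size(paste0(pre, ".bed")))
    writeBin(c(raw, as.raw(0)), paste0(pre, ".bed"))  # extra data byte
    expect_error(readPlink(pre), "offset 3")
})

test_that("the 2-bit genotype codes decode per the PLINK 1.9 layout", {
    # one marker, 4 samples: codes 00 (hom A1), 01 (missing), 10 (het),
    # 11 (hom A2) packed into one byte, little-endian 2-bit fields
    pre <- file.path(withr_like_tempdir(), "codes")
    writeLines(sprintf("s%d\ts%d\t0\t0\t0\t-9", 1:4, 1:4), paste0(pre, ".fam"))
    writeLines("1\tm1\t0\t1000\tA\tG", paste0(pre, ".bim"))
    byte <- as.raw(0x00 + 0x01 * 4 + 0x02 * 16 + 0x03 * 64)
    writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), byte), paste0(pre, ".bed"))
    g <- readPlink(pre)
    expect_equal(unname(dosages(g)[, 1]), c(2, NA, 1, 0))
})

test_that("ped/map text input yields minor-allele dosages", {
    pre <- file.path(withr_like_tempdir(), "txt")
    writeLines(c("1 m1 0 1000", "1 m2 0 2000"), paste0(pre, ".map"))
    writeLines(c("f1 s1 0 0 0 -9 A A G G",
                 "f2 s2 0 0 0 -9 A G G G",
                 "f3 s3 0 0 0 -9 A A 0 0"),
               paste0(pre, ".ped"))
    g <- readPlink(pre)
    expect_equal(unname(dosages(g)[, "m1"]), c(0, 1, 0))  # G is minor at m1
    expect_equal(unname(dosages(g)[, "m2"]), c(2, 2, NA)) # monomorphic G/G
})

test_that("VCF genotypes parse to ALT counts with missing and half calls", {
    f <- file.path(withr_like_tempdir(), "t.vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
        "1\t100\tv1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
        "1\t200\tv2\tG\tT\t.\tPASS\t.\tGT\t./.\t0|1\t./1",
        "2\t150\tv3\tT\tA\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1"), f)
    g <- readVcfGeno(f)
    expect_equal(unname(dosages(g)[, "v1"]), c(0, 1, 2))
    expect_equal(unname(dosages(g)[, "v2"]), c(NA, 1, NA))
    mk <- markerInfo(g)
    expect_equal(mk$chrom[mk$id == "v3"], "2")
    expect_equal(mk$pos[mk$id == "v3"], 150L)
    expect_equal(mk$a1[mk$id == "v1"], "C")   # ALT is the counted allele
    expect_equal(mk$a2[mk$id == "v1"], "A")
    # VCF writer round-trips
    f2 <- file.path(dirname(f), "t2.vcf")
    writeVcfGeno(g, f2)
    expect_identical(dosages(readVcfGeno(f2)), dosages(g))
})

test_that("multi-allelic records are rejected or dropped per configuration", {
    f <- file.path(withr_like_tempdir(), "ma.vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
        "1\t100\tv1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1",
        "1\t200\tv2\tG\tT,C\t.\tPASS\t.\tGT\t0/1\t1/2"), f)
    expect_error(readVcfGeno(f), "multi-allelic")
    g <- readVcfGeno(f, multiallelic = "drop")
    expect_equal(nMarkers(g), 1L)
})

test_that("HWE exact test matches enumeration and chi-square oracles", {
    cases <- list(c(3, 5, 2), c(7, 1, 2), c(5, 0, 5), c(240, 520, 240),
                  c(12, 3, 30), c(1, 9, 1))
    for (cs in cases)
        expect_equal(hweExactTest(cs[1], cs[2], cs[3]),
                     oracleHwe(cs[1], cs[2], cs[3]), tolerance = 1e-10)
    expect_equal(hweExactTest(3, 5, 2), 1.0)                 # modal het
    expect_equal(hweExactTest(7, 1, 2), 0.046439628483, tolerance = 1e-9)
    expect_identical(hweExactTest(0, 0, 17), 1.0)            # monomorphic
    # large balanced counts approach the chi-square p
    expect_lt(abs(hweExactTest(250, 500, 250) -
                  oracleHweChisq(250, 500, 250)), 0.02)
    expect_error(hweExactTest(-1, 2, 3), "counts")
})

test_that("HWE exact test is symmetric in the homozygote classes", {
    set.seed(8)
    for (i in 1:25) {
        cs <- rpois(3, 12)
        if (sum(cs) == 0) next
        expect_equal(hweExactTest(cs[1], cs[2], cs[3]),
                     hweExactTest(cs[3], cs[2], cs[1]), tolerance = 1e-12)
    }
})

test_that("QC filters run in the fixed order with hand-counted removals", {
    # 10 markers x 120 samples: markers 1-2 below the 0.5% MAF floor,
    # marker 3 with call rate 0.89, the rest clean at MAF 0.5 in perfect HWE
    n <- 120
    d <- matrix(rep(c(0, 1, 1, 2), n / 4), n, 10)
    d[, 1] <- c(1, rep(0, n - 1))        # MAF 1/240 ~ 0.0042
    d[, 2] <- c(1, rep(0, n - 1))
    d[1:13, 3] <- NA                     # call rate 107/120 ~ 0.89
    g <- makeGeno(d)
    qc <- applyQc(g, QcThresholds(0.95, 0.97, 0.005, 1e-6))
    expect_equal(nMarkers(qc$genotypes), 7L)
    expect_equal(qc$log$removed[qc$log$step == "snp_call_rate"], 1L)
    expect_equal(qc$log$removed[qc$log$step == "sample_call_rate"], 0L)
    expect_equal(qc$log$removed[qc$log$step == "maf"], 2L)
    expect_equal(qc$log$removed[qc$log$step == "hwe"], 0L)
})

test_that("a marker violating HWE is removed and attributed to the hwe step", {
    set.seed(4)
    d <- sapply(runif(5, 0.3, 0.7), function(p) rbinom(60, 2, p))
    d[, 3] <- rep(c(0, 2), 30)           # no heterozygotes at p = 0.5
    g <- makeGeno(d)
    gcount <- c(sum(d[, 3] == 2), sum(d[, 3] == 1), sum(d[, 3] == 0))
    expect_lt(hweExactTest(gcount[1], gcount[2], gcount[3]), 1e-8)
    qc <- applyQc(g)
    expect_equal(qc$removedIds$hwe, "m0003")
    expect_equal(nMarkers(qc$genotypes), 4L)
})

test_that("applyQc is idempotent and leaves a clean panel unchanged", {
    g <- makeGeno(sapply(runif(8, 0.3, 0.7), function(p) rbinom(80, 2, p)))
    qc1 <- applyQc(g)
    qc2 <- applyQc(qc1$genotypes)
    expect_identical(dosages(qc2$genotypes), dosages(qc1$genotypes))
    expect_true(all(qc2$log$removed == 0))
    d <- matrix(rep(c(0, 1, 1, 2), 25), 100, 4)  # MAF 0.5, HWE-exact counts
    gClean <- makeGeno(d)
    expect_identical(dosages(applyQc(gClean)$genotypes), dosages(gClean))
})
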