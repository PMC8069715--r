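test_that("identical seed reproduces the bundle exactly, on disk too", {
    s1 <- simulateLocus(locusConfig(seed = 11))
    s2 <- simulateLocus(locusConfig(seed = 11))
    expect_identical(SummarizedExperiment::assay(methylome(s1), "ratio"),
                     SummarizedExperiment::assay(methylome(s2), "ratio"))
    expect_identical(as.data.frame(rnaCounts(s1)), as.data.frame(rnaCounts(s2)))
    expect_identical(as.character(locusSequence(s1)),
                     as.character(locusSequence(s2)))
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeSimulation(s1, d1); writeSimulation(s2, d2)
    expect_identical(sort(list.files(d1)), sort(list.files(d2)))
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    s3 <- simulateLocus(locusConfig(seed = 12))
    expect_false(identical(
        SummarizedExperiment::assay(methylome(s1), "ratio"),
        SummarizedExperiment::assay(methylome(s3), "ratio")))
})

test_that("planted DMR methylation contrast matches the configured means", {
    sim <- simulateLocus(locusConfig(seed = 3))
    cfg <- simTruth(sim)
    me <- methylome(sim)
    pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(me))
    d <- siteDelta(me)
    for (i in seq_len(nrow(cfg@dmrs))) {
        inD <- pos >= cfg@dmrs$start[i] & pos <= cfg@dmrs$end[i]
        expect_gte(sum(inD), 10)
        expect_lt(abs(mean(d[inD]) - 0.45), 0.05)
    }
    # background sites carry no systematic contrast
    bg <- pos < min(cfg@dmrs$start)
    expect_lt(abs(mean(d[bg])), 0.05)
})

test_that("biallelic expression stays near 50:50 at deep coverage", {
    # the +/- 0.1 allowance is a ~3-sigma binomial bound at depth 200, so it
    # is asserted per site on a two-site configuration; the across-tissue
    # mean gets a law-of-large-numbers bound
    cfg <- locusConfig(expressionMode = "biallelic", rnaDepthMean = 200,
                       overdispersion = 1e4, tissues = c("Ad", "Ln"),
                       snps = data.frame(pos = c(21341446, 21349510),
                                         ref = c("C", "G"),
                                         alt = c("T", "C"),
                                         rsId = NA),
                       individuals = "P1",
                       genotypes = matrix(c("C|T", "G|C"), ncol = 1),
                       seed = 5)
    sim <- simulateLocus(cfg)
    rna <- rnaCounts(sim)
    pat <- paternalAlleles(cfg)
    patFracs <- numeric()
    for (i in seq_len(nrow(cfg@snps))) {
        r <- rna[rna$pos == cfg@snps$pos[i], ]
        pf <- ifelse(pat[i, 1] == cfg@snps$ref[i], r$refCount, r$altCount) /
              (r$refCount + r$altCount)
        expect_true(all(abs(pf - 0.5) < 0.1))
        patFracs <- c(patFracs, pf)
    }
    expect_lt(abs(mean(patFracs) - 0.5), 0.05)
})

test_that("null methylomes have matched group means and no planted signal", {
    cfg <- locusConfig(locusStart = 1, locusEnd = 200000, cpgPerKb = 10,
                       dmrs = NULL, snps = NULL, genotypes = NULL,
                       islandInterval = NULL,
                       ctcfPeakCenters = c(40000, 120000),
                       transcriptUnit = c(50000, 110000), seed = 21)
    sim <- simulateNullMethylomes(cfg)
    me <- methylome(sim)
    expect_gte(nrow(me), 1900)
    expect_equal(nrow(simTruth(sim)@dmrs), 0L)
    mA <- mean(groupRatios(me, "A"))
    mB <- mean(groupRatios(me, "B"))
    expect_lt(abs(mA - mB), 0.02)
})

test_that("a locus configured without CpGs yields empty tables, not errors", {
    cfg <- locusConfig(cpgPerKb = 0, dmrs = NULL, seed = 1)
    sim <- simulateLocus(cfg)
    expect_equal(nrow(methylome(sim)), 0L)
    expect_gt(nrow(rnaCounts(sim)), 0L)
})

test_that("monoallelic RNA counts are phase-consistent with the paternal haplotype", {
    cfg <- locusConfig(seed = 13)
    sim <- simulateLocus(cfg)
    rna <- rnaCounts(sim)
    pat <- paternalAlleles(cfg)
    checked <- 0L
    for (j in seq_along(cfg@individuals)) {
        for (i in seq_len(nrow(cfg@snps))) {
            gt <- strsplit(cfg@genotypes[i, j], "|", fixed = TRUE)[[1]]
            if (gt[1] == gt[2]) next
            r <- rna[rna$pos == cfg@snps$pos[i] &
                     rna$sampleId == cfg@individuals[j], ]
            major <- ifelse(r$refCount >= r$altCount,
                            cfg@snps$ref[i], cfg@snps$alt[i])
            expect_true(all(major == pat[i, j]))
            checked <- checked + nrow(r)
        }
    }
    expect_gte(checked, 20L)
    # mean paternal fraction respects the configured purity floor
    het <- rna$refCount + rna$altCount > 0
    expect_gte(mean(apply(cbind(rna$refCount, rna$altCount)[het, ], 1, max) /
                    (rna$refCount + rna$altCount)[het]), cfg@purity)
})

test_that("invalid configurations are rejected", {
    expect_error(locusConfig(dmrs = data.frame(
        start = c(100, 150), end = c(200, 250), meanA = 0.9, meanB = 0.4),
        locusStart = 1, locusEnd = 1000, snps = NULL, genotypes = NULL,
        islandInterval = NULL, ctcfPeakCenters = 500,
        transcriptUnit = c(300, 600)), "overlap")
    expect_error(locusConfig(locusStart = 1, locusEnd = 1000,
        dmrs = NULL, islandInterval = NULL, ctcfPeakCenters = 500,
        transcriptUnit = c(300, 600),
        snps = data.frame(pos = 5000, ref = "A", alt = "G", rsId = NA),
        individuals = "P1", genotypes = matrix("A|G")), "span")
    expect_error(locusConfig(backgroundMean = 1.4), "\\[0, 1\\]")
})
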