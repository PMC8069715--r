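test_that("siteDelta is the difference of group means, NA when replicates are short", {
    me1 <- methylomeExperiment(
        ratios = cbind(a1 = 1.0, a2 = 0.9, a3 = 0.95,
                       b1 = 0.50, b2 = 0.45, b3 = 0.55),
        chrom = "chr1", pos = 100, group = c("PA", "PA", "PA", "CN", "CN", "CN"))
    expect_equal(siteDelta(me1), 0.45)
    me2 <- meFromMeans(c(0.3, 0.8), c(0.3, 0.8))
    expect_equal(siteDelta(me2), c(0, 0))
    me3 <- methylomeExperiment(
        ratios = cbind(a1 = c(0.9, NA), a2 = c(0.8, NA), b1 = c(0.4, 0.5),
                       b2 = c(0.5, 0.4)),
        chrom = "chr1", pos = c(100, 200), group = c("PA", "PA", "CN", "CN"))
    expect_equal(is.na(siteDelta(me3)), c(FALSE, TRUE))
})

test_that("CpG flagging uses a strict threshold and keeps the sign", {
    expect_identical(flagDmCpgs(c(0.45, 0.2, -0.35, NA, 0.2000001)),
                     c(1L, 0L, -1L, 0L, 1L))
})

test_that("segmentation emits maximal close-packed same-sign runs", {
    pos <- seq(1, by = 50, length.out = 10)
    cand <- segmentCandidates(pos, rep(1L, 10))
    expect_equal(nrow(cand), 1L)
    expect_equal(cand$nDmCpgs, 10L)
    expect_equal(cand$end - cand$start + 1, 451)

    expect_equal(nrow(segmentCandidates(seq(1, by = 50, length.out = 9),
                                        rep(1L, 9))), 0L)

    # a gap of exactly maxGap splits the run (strict "less than")
    pos12 <- c(seq(1, by = 50, length.out = 6),
               seq(551, by = 50, length.out = 6))
    expect_equal(diff(pos12)[6], 300)
    expect_equal(nrow(segmentCandidates(pos12, rep(1L, 12), minCpgs = 10)), 0L)
    split6 <- segmentCandidates(pos12, rep(1L, 12), minCpgs = 6)
    expect_equal(nrow(split6), 2L)

    # sign changes break runs
    expect_equal(nrow(segmentCandidates(pos, c(rep(1L, 5), rep(-1L, 5)),
                                        minCpgs = 5)), 2L)
    expect_error(segmentCandidates(c(5, 1), c(1L, 1L)), "sorted")
})

test_that("segmentation equals the brute-force window scan", {
    for (s in 1:10) {
        set.seed(s)
        n <- 60
        pos <- cumsum(sample(20:400, n, replace = TRUE))
        flags <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                        prob = c(0.3, 0.3, 0.4))
        got <- segmentCandidates(pos, flags, maxGap = 300, minCpgs = 3)
        want <- bruteForceCandidates(pos, flags, maxGap = 300, minCpgs = 3)
        expect_equal(got[, c("start", "end", "nDmCpgs")], want,
                     ignore_attr = TRUE)
    }
})

test_that("looser thresholds never lose candidate coverage", {
    for (s in 1:6) {
        set.seed(100 + s)
        n <- 120
        pos <- cumsum(sample(20:250, n, replace = TRUE))
        deltas <- stats::rnorm(n, 0, 0.25)
        strict <- segmentCandidates(pos, flagDmCpgs(deltas, 0.3),
                                    maxGap = 250, minCpgs = 3)
        loose1 <- segmentCandidates(pos, flagDmCpgs(deltas, 0.2),
                                    maxGap = 250, minCpgs = 3)
        loose2 <- segmentCandidates(pos, flagDmCpgs(deltas, 0.3),
                                    maxGap = 400, minCpgs = 3)
        for (loose in list(loose1, loose2)) {
            if (!nrow(strict)) next
            covered <- vapply(seq_len(nrow(strict)), function(i)
                any(loose$start <= strict$start[i] &
                    loose$end >= strict$end[i]), logical(1))
            expect_true(all(covered))
        }
    }
})

test_that("region test: degenerate, complete-separation and BH behaviour", {
    # identical per-CpG means in both groups -> p = 1
    meConst <- meFromMeans(rep(0.5, 10), rep(0.5, 10))
    cand <- segmentCandidates(GenomicRanges::start(
        SummarizedExperiment::rowRanges(meConst)), rep(1L, 10), minCpgs = 10)
    expect_equal(testRegions(cand, meConst)$pValue, 1)

    # complete separation of 10 vs 10 per-CpG means: exact MWU p
    set.seed(1)
    me <- meFromMeans(stats::runif(10, 0.8, 0.95), stats::runif(10, 0.3, 0.5))
    cand <- segmentCandidates(GenomicRanges::start(
        SummarizedExperiment::rowRanges(me)), rep(1L, 10), minCpgs = 10)
    res <- testRegions(cand, me)
    expect_equal(res$pValue, 2 / choose(20, 10), tolerance = 1e-12)
    expect_equal(res$deltaAve, mean(groupRatios(me, "A")) -
                                mean(groupRatios(me, "B")))

    expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
                 c(0.03, 0.03, 0.04))
    for (s in 1:5) {
        set.seed(s)
        p <- stats::runif(20)
        expect_equal(stats::p.adjust(p, "BH"), bhStepUp(p))
    }
})

test_that("exact Mann-Whitney path equals exhaustive rank enumeration", {
    for (s in 1:8) {
        set.seed(s)
        k <- sample(3:8, 1)
        me <- meFromMeans(stats::runif(k), stats::runif(k))
        cand <- segmentCandidates(GenomicRanges::start(
            SummarizedExperiment::rowRanges(me)), rep(1L, k), minCpgs = k)
        got <- testRegions(cand, me)$pValue
        want <- mannWhitneyEnumP(rowMeans(groupRatios(me, "A")),
                                 rowMeans(groupRatios(me, "B")))
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("planted DMRs are recovered with tight bounds and the right direction", {
    cfg <- locusConfig(seed = 42)
    sim <- simulateLocus(cfg)
    me <- methylome(sim)
    pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(me))
    dmrs <- callDmrs(me)
    expect_equal(length(dmrs), nrow(cfg@dmrs))
    expect_true(all(dmrs$direction == "maternal_hyper"))
    expect_true(all(dmrs$qValue < 0.05))
    expect_true(all(abs(dmrs$deltaAve) > 0.2))
    o <- order(GenomicRanges::start(dmrs))
    for (i in seq_len(nrow(cfg@dmrs))) {
        spacing <- 1000 / cfg@dmrs$cpgPerKb[i]
        inPlant <- pos[pos >= cfg@dmrs$start[i] & pos <= cfg@dmrs$end[i]]
        expect_lte(abs(GenomicRanges::start(dmrs)[o[i]] - min(inPlant)),
                   2 * spacing)
        expect_lte(abs(GenomicRanges::end(dmrs)[o[i]] - max(inPlant)),
                   2 * spacing)
        expect_gte(dmrs$nDmCpgs[o[i]], 10)
    }
})

test_that("the caller stays quiet on null methylomes", {
    nullCfg <- function(seed) locusConfig(
        locusStart = 1, locusEnd = 200000, cpgPerKb = 10,
        dmrs = NULL, snps = NULL, genotypes = NULL, islandInterval = NULL,
        ctcfPeakCenters = c(40000, 120000),
        transcriptUnit = c(50000, 110000), seed = seed)
    hits <- vapply(1:10, function(s)
        length(callDmrs(methylome(simulateNullMethylomes(nullCfg(s))))),
        integer(1))
    # strict check happens in the 50-replicate calibration; here: no blow-up
    expect_lte(mean(hits), 0.25)
})

test_that("DMR calling needs two groups and survives empty input", {
    expect_error(methylomeExperiment(matrix(0.5, 2, 2), "chr1", c(1, 2),
                                     group = c("PA", "PA")), "two-level")
    cfg <- locusConfig(cpgPerKb = 0, dmrs = NULL, seed = 1)
    expect_equal(length(callDmrs(methylome(simulateLocus(cfg)))), 0L)
})
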