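test_that("the rounding convention reproduces every printed percent exactly", {
    counts <- readAlleleCounts(plagl1CountsFile())
    want <- printedPercents()
    expect_equal(nrow(counts), nrow(want))
    got <- allelicFraction(counts$refCount, counts$altCount)
    keepR <- !is.na(want$refPct)
    keepA <- !is.na(want$altPct)
    expect_identical(got$percentRef[keepR], as.integer(want$refPct[keepR]))
    expect_identical(got$percentAlt[keepA], as.integer(want$altPct[keepA]))
    # halves round away from zero: 6/16 prints 38/63 (sums to 101)
    expect_identical(percentRound(c(37.5, 62.5, -37.5)), c(38L, 63L, -38L))
})

test_that("genotype classification matches the published informative calls", {
    counts <- readAlleleCounts(plagl1CountsFile())
    g <- classifyGenotype(counts)
    expect_true(all(g$call == "heterozygous"))  # all printed gDNA rows informative
    p1 <- g[g$pos == 21341446 & g$sampleId == "P1", ]
    expect_equal(c(p1$percentRef, p1$percentAlt), c(45L, 55L))
    p3 <- g[g$pos == 21349510 & g$sampleId == "P3", ]
    expect_equal(c(p3$percentRef, p3$percentAlt), c(32L, 68L))

    d <- alleleCountSet(data.frame(chrom = "chr1", pos = 1:3, ref = "A",
        alt = "G", sampleId = "S", source = "gDNA",
        refCount = c(22L, 0L, 3L), altCount = c(0L, 0L, 2L)))
    expect_equal(classifyGenotype(d)$call,
                 c("homozygous", "ambiguous", "ambiguous"))
})

test_that("genotype and expression classification commute with allele swap", {
    set.seed(8)
    for (i in 1:20) {
        rc <- sample(0:60, 2)
        d <- alleleCountSet(data.frame(chrom = "chr1", pos = 1, ref = "A",
            alt = "G", sampleId = "S", source = "gDNA",
            refCount = rc[1], altCount = rc[2]))
        dSwap <- alleleCountSet(data.frame(chrom = "chr1", pos = 1, ref = "A",
            alt = "G", sampleId = "S", source = "gDNA",
            refCount = rc[2], altCount = rc[1]))
        expect_identical(classifyGenotype(d)$call, classifyGenotype(dSwap)$call)
        r <- alleleCountSet(data.frame(chrom = "chr1", pos = 1, ref = "A",
            alt = "G", sampleId = "S", source = "RNA", tissue = "Ad",
            refCount = rc[1], altCount = rc[2]))
        rSwap <- alleleCountSet(data.frame(chrom = "chr1", pos = 1, ref = "A",
            alt = "G", sampleId = "S", source = "RNA", tissue = "Ad",
            refCount = rc[2], altCount = rc[1]))
        map <- c(monoallelic_ref = "monoallelic_alt",
                 monoallelic_alt = "monoallelic_ref",
                 biased = "biased", biallelic = "biallelic",
                 low_coverage = "low_coverage")
        expect_identical(unname(map[classifyAllelicExpression(r)$call]),
                         classifyAllelicExpression(rSwap)$call)
    }
})

test_that("the informative screen finds the published sites and simulated truth", {
    counts <- readAlleleCounts(plagl1CountsFile())
    catalog <- readVariantCatalog(plagl1CatalogFile())
    inf <- screenInformative(counts, catalog = catalog)
    expect_equal(nrow(inf), 7L)
    published <- unique(inf$rsId[inf$rsId != "NR"])
    expect_setequal(published,
                    c("rs331051321", "rs331477147", "rs327656939"))
    expect_equal(sum(inf$rsId == "rs331477147"), 3L)  # het in all three pigs
    expect_equal(inf$sampleId[inf$rsId == "NR"], "P2")

    empty <- alleleCountSet(data.frame(chrom = character(), pos = numeric(),
        ref = character(), alt = character(), sampleId = character(),
        source = character(), refCount = integer(), altCount = integer()))
    expect_equal(nrow(screenInformative(empty)), 0L)

    cfg <- locusConfig(gdnaDepthMean = 30, seed = 17)
    sim <- simulateLocus(cfg)
    inf <- screenInformative(gdnaCounts(sim))
    trueHet <- which(apply(cfg@genotypes, c(1, 2), function(g) {
        a <- strsplit(g, "|", fixed = TRUE)[[1]]; a[1] != a[2]
    }), arr.ind = TRUE)
    wantPairs <- paste(cfg@snps$pos[trueHet[, 1]],
                       cfg@individuals[trueHet[, 2]])
    expect_setequal(paste(inf$pos, inf$sampleId), wantPairs)

    # regions restriction drops out-of-region sites
    reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(21341000, 21350000))
    inf2 <- screenInformative(counts, catalog = catalog, regions = reg)
    expect_true(all(inf2$pos <= 21350000))
    expect_equal(nrow(inf2), 5L)
})

test_that("allelic fractions follow the printed convention and guard zero depth", {
    expect_equal(unlist(allelicFraction(6, 10)),
                 c(refFraction = 0.375, percentRef = 38, percentAlt = 63))
    expect_equal(allelicFraction(2, 35)$percentAlt, 95L)
    expect_equal(allelicFraction(0, 26)[, c("percentRef", "percentAlt")],
                 data.frame(percentRef = 0L, percentAlt = 100L))
    expect_error(allelicFraction(0, 0), class = "imprintKit_zero_depth")
})

test_that("expression classification matches the published tissue calls", {
    counts <- readAlleleCounts(plagl1CountsFile())
    ase <- classifyAllelicExpression(counts)
    lungP1 <- ase[ase$pos == 21341446 & ase$sampleId == "P1" &
                  ase$tissue == "Ln", ]
    expect_equal(lungP1$call, "monoallelic_alt")
    expect_equal(c(lungP1$percentRef, lungP1$percentAlt), c(5L, 95L))
    ovP3 <- ase[ase$pos == 21368747 & ase$tissue == "Ov", ]
    expect_equal(ovP3$call, "monoallelic_ref")
    # every published tissue call with usable depth is monoallelic
    expect_true(all(grepl("^monoallelic", ase$call)))

    mid <- alleleCountSet(data.frame(chrom = "chr1", pos = 1, ref = "A",
        alt = "G", sampleId = "S", source = "RNA", tissue = "Ad",
        refCount = 18L, altCount = 17L))
    expect_equal(classifyAllelicExpression(mid)$call, "biallelic")
    skewed <- alleleCountSet(data.frame(chrom = "chr1", pos = 1, ref = "A",
        alt = "G", sampleId = "S", source = "RNA", tissue = "Ad",
        refCount = 72L, altCount = 28L))
    expect_equal(classifyAllelicExpression(skewed)$call, "biased")
    shallow <- alleleCountSet(data.frame(chrom = "chr1", pos = 1, ref = "A",
        alt = "G", sampleId = "S", source = "RNA", tissue = "Ad",
        refCount = 4L, altCount = 3L))
    expect_equal(classifyAllelicExpression(shallow)$call, "low_coverage")
})

test_that("reported binomial p equals pmf-sum enumeration for totals <= 25", {
    for (n in c(5L, 12L, 20L, 25L)) {
        for (k in 0:n) {
            d <- alleleCountSet(data.frame(chrom = "chr1", pos = 1, ref = "A",
                alt = "G", sampleId = "S", source = "RNA", tissue = "Ad",
                refCount = k, altCount = n - k))
            expect_equal(classifyAllelicExpression(d)$pBinomial,
                         binomEnumP(k, n), tolerance = 1e-12)
        }
    }
})

test_that("maintenance assessment verdicts consistency across tissues", {
    counts <- readAlleleCounts(plagl1CountsFile())
    rep <- assessMaintenance(classifyAllelicExpression(counts))
    p3 <- rep[["P3"]]$sites
    ri <- p3[p3$site == "chr1:21349510", ]
    expect_true(ri$consistent)
    expect_equal(ri$expressedAllele, "ref")
    expect_equal(ri$nMonoallelic, 4L)
    expect_true(rep[["P3"]]$allSitesMonoallelic)

    contra <- alleleCountSet(data.frame(chrom = "chr1", pos = 10,
        ref = "A", alt = "G", sampleId = "X", source = "RNA",
        tissue = c("Ad", "Br"), refCount = c(30L, 0L), altCount = c(0L, 30L)))
    r2 <- assessMaintenance(classifyAllelicExpression(contra))
    expect_false(r2[["X"]]$sites$consistent)

    none <- alleleCountSet(data.frame(chrom = "chr1", pos = 10,
        ref = "A", alt = "G", sampleId = "Y", source = "RNA",
        tissue = "Ad", refCount = 1L, altCount = 0L))
    expect_equal(assessMaintenance(classifyAllelicExpression(none))[["Y"]]$reason,
                 "no usable calls")
})

test_that("a reversed-imprint tissue is flagged as the discordant one", {
    cfg <- locusConfig(tissueModes = c(Hr = "monoallelic_maternal"), seed = 23)
    sim <- simulateLocus(cfg)
    rep <- assessMaintenance(classifyAllelicExpression(rnaCounts(sim)))
    pat <- paternalAlleles(cfg)
    for (j in seq_along(cfg@individuals)) {
        id <- cfg@individuals[j]
        for (i in seq_len(nrow(cfg@snps))) {
            gt <- strsplit(cfg@genotypes[i, j], "|", fixed = TRUE)[[1]]
            if (gt[1] == gt[2]) next
            s <- rep[[id]]$sites
            row <- s[s$site == paste0("chr1:", cfg@snps$pos[i]), ]
            expect_false(row$consistent)
            expect_true(grepl("Hr", row$discordantTissues))
        }
    }
})
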