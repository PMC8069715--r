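#' Build a synthetic imprinted-locus configuration
#'
#' Defaults describe a virtual locus modelled on the porcine PLAGL1 region:
#' a 90-kb span on chr1 with background methylation around 0.7 in both
#' groups, a promoter/CpG-island DMR and a small intronic DMR that are
#' maternally hypermethylated (group means 0.90 vs 0.45), four exonic SNPs
#' with the published coordinates and phased genotypes whose paternal allele
#' is the expressed one, a paternally monoallelic transcription unit, and a
#' CTCF peak on each side of the unit. See the package vignette for the
#' rationale behind each default.
#'
#' @param chrom,locusStart,locusEnd locus coordinates (1-based inclusive).
#' @param nReplicates methylome replicates per group.
#' @param backgroundMean background methylation ratio for both groups.
#' @param betaConcentration beta concentration of replicate scatter.
#' @param coverageMean mean bisulfite read depth per CpG.
#' @param cpgPerKb CpG density outside planted DMRs (CpGs per kb).
#' @param dmrs planted DMRs (see \linkS4class{LocusConfig}); \code{NULL}
#'   for none.
#' @param snps,individuals,genotypes SNP sites and phased genotypes.
#' @param transcriptUnit transcription-unit interval.
#' @param expressionMode default expression mode of the unit.
#' @param tissueModes named per-tissue mode overrides (e.g.
#'   \code{c(Br = "monoallelic_maternal")} for a reversed-imprint tissue).
#' @param tissues tissue labels receiving RNA allele counts.
#' @param rnaDepthMean,gdnaDepthMean mean allele-count depths.
#' @param overdispersion beta-binomial concentration of allele fractions.
#' @param purity minimum expected paternal-allele fraction under monoallelic
#'   expression.
#' @param ctcfPeakCenters,peakFold,peakWidth ChIP peak geometry.
#' @param binSize,chipNoiseMean coverage-track bin size and background.
#' @param precipDepthMean mean precipitate allele-count depth.
#' @param islandInterval planted CpG-rich segment, or \code{NULL}.
#' @param seed integer seed.
#' @return a validated \linkS4class{LocusConfig}.
#' @export
locusConfig <- function(chrom = "chr1",
                        locusStart = 21290000, locusEnd = 21380000,
                        nReplicates = 3,
                        backgroundMean = 0.7,
                        betaConcentration = 20,
                        coverageMean = 30,
                        cpgPerKb = 10,
                        dmrs = data.frame(
                            start = c(21303256, 21337135),
                            end = c(21305675, 21337358),
                            meanA = 0.90, meanB = 0.45,
                            cpgPerKb = c(20, 45)),
                        snps = data.frame(
                            pos = c(21341446, 21349510, 21365021, 21368747),
                            ref = c("C", "G", "T", "A"),
                            alt = c("T", "C", "A", "G"),
                            rsId = c("rs331051321", "rs331477147",
                                     NA, "rs327656939")),
                        individuals = c("P1", "P2", "P3"),
                        genotypes = rbind(
                            c("C|T", "C|T", "T|T"),
                            c("G|C", "G|C", "C|G"),
                            c("T|T", "A|T", "T|T"),
                            c("A|A", "A|A", "G|A")),
                        transcriptUnit = c(21304000, 21369500),
                        expressionMode = "monoallelic_paternal",
                        tissueModes = character(),
                        tissues = c("Ad", "Ln", "Hr", "Ov"),
                        rnaDepthMean = 60,
                        gdnaDepthMean = 25,
                        overdispersion = 100,
                        purity = 0.98,
                        ctcfPeakCenters = c(21302000, 21370000),
                        peakFold = 10,
                        peakWidth = 800,
                        binSize = 200,
                        chipNoiseMean = 20,
                        precipDepthMean = 150,
                        islandInterval = c(21303765, 21304604),
                        seed = 1) {
    if (is.null(dmrs))
        dmrs <- data.frame(start = numeric(), end = numeric(),
                           meanA = numeric(), meanB = numeric())
    if (!"cpgPerKb" %in% names(dmrs))
        dmrs$cpgPerKb <- rep(NA_real_, nrow(dmrs))
    if (is.null(snps))
        snps <- data.frame(pos = numeric(), ref = character(),
                           alt = character(), rsId = character())
    if (is.null(genotypes))
        genotypes <- matrix(character(), nrow(snps), length(individuals))
    new("LocusConfig", chrom = chrom,
        locusStart = as.numeric(locusStart), locusEnd = as.numeric(locusEnd),
        nReplicates = as.integer(nReplicates),
        backgroundMean = backgroundMean,
        betaConcentration = betaConcentration, coverageMean = coverageMean,
        cpgPerKb = cpgPerKb, dmrs = dmrs, snps = snps,
        individuals = individuals,
        genotypes = if (nrow(snps))
            matrix(genotypes, nrow = nrow(snps),
                   dimnames = list(NULL, individuals))
        else matrix(character(), 0L, length(individuals),
                    dimnames = list(NULL, individuals)),
        transcriptUnit = as.numeric(transcriptUnit),
        expressionMode = expressionMode,
        tissueModes = tissueModes, tissues = tissues,
        rnaDepthMean = rnaDepthMean, gdnaDepthMean = gdnaDepthMean,
        overdispersion = overdispersion, purity = purity,
        ctcfPeakCenters = as.numeric(ctcfPeakCenters),
        peakFold = peakFold, peakWidth = peakWidth,
        binSize = binSize, chipNoiseMean = chipNoiseMean,
        precipDepthMean = precipDepthMean,
        islandInterval = if (is.null(islandInterval)) numeric() else
            as.numeric(islandInterval),
        seed = as.integer(seed))
}

# CpG positions on a jittered lattice: spacing 1000/density with uniform
# jitter of a quarter spacing, so no background gap can reach three times
# the nominal spacing (CpG spacing in real loci is clustered, not Poisson).
.latticePositions <- function(start, end, perKb) {
    if (perKb <= 0) return(numeric())
    s <- 1000 / perKb
    k <- floor((end - start + 1) / s)
    if (k < 1) return(numeric())
    p <- start + s / 2 + (seq_len(k) - 1) * s +
        stats::runif(k, -s / 4, s / 4)
    sort(round(p[p >= start & p <= end]))
}

.rbetaMean <- function(n, mean, conc) {
    m <- pmin(pmax(mean, 1e-6), 1 - 1e-6)
    rbeta(n, m * conc, (1 - m) * conc)
}

.splitGenotype <- function(gt) strsplit(gt, "|", fixed = TRUE)[[1]]

#' Simulate a full imprinted-locus bundle
#'
#' Generates, from one seeded configuration: per-CpG methylation ratios for
#' both groups (beta-distributed replicate means thinned through binomial
#' read sampling at Poisson coverage), genomic-DNA allele depths at every
#' SNP, per-tissue RNA allele depths that are phase-consistent with each
#' individual's paternal haplotype under monoallelic expression, ChIP input
#' and precipitate coverage tracks with Gaussian-shaped CTCF peaks,
#' precipitate allele counts at the SNP sites, and a locus sequence with a
#' CpG-depleted background and one planted CpG-rich segment. The same
#' configuration and seed always reproduce the bundle exactly.
#'
#' @param config a \linkS4class{LocusConfig}.
#' @return a \linkS4class{LocusSimulation}.
#' @examples
#' sim <- simulateLocus(locusConfig(seed = 42))
#' sim
#' @export
simulateLocus <- function(config) {
    stopifnot(is(config, "LocusConfig"))
    validObject(config)
    set.seed(config@seed)
    ch <- config@chrom
    span <- c(config@locusStart, config@locusEnd)

    ## CpG positions: background lattice minus DMR footprints, plus DMR lattices
    pos <- .latticePositions(span[1], span[2], config@cpgPerKb)
    d <- config@dmrs
    for (i in seq_len(nrow(d))) {
        pos <- pos[pos < d$start[i] | pos > d$end[i]]
        dens <- if (is.na(d$cpgPerKb[i])) config@cpgPerKb else d$cpgPerKb[i]
        pos <- c(pos, .latticePositions(d$start[i], d$end[i], dens))
    }
    pos <- sort(unique(pos))

    ## per-site group means
    meanA <- rep(config@backgroundMean, length(pos))
    meanB <- meanA
    for (i in seq_len(nrow(d))) {
        inD <- pos >= d$start[i] & pos <= d$end[i]
        meanA[inD] <- d$meanA[i]
        meanB[inD] <- d$meanB[i]
    }

    nr <- config@nReplicates
    nsite <- length(pos)
    # ratio-level noise model: per-replicate ratios are beta draws around the
    # site mean; read counts are derived, rounded metadata kept consistent
    # with the ratio to within the reader's 0.5/total tolerance
    drawGroup <- function(means) {
        ratio <- matrix(NA_real_, nsite, nr)
        meth <- tot <- matrix(NA_integer_, nsite, nr)
        for (r in seq_len(nr)) {
            p <- .rbetaMean(nsite, means, config@betaConcentration)
            cv <- rpois(nsite, config@coverageMean) + 1L
            ratio[, r] <- p
            meth[, r] <- as.integer(round(p * cv)); tot[, r] <- cv
        }
        list(ratio = ratio, meth = meth, tot = tot)
    }
    ga <- drawGroup(meanA)
    gb <- drawGroup(meanB)
    me <- methylomeExperiment(
        ratios = cbind(ga$ratio, gb$ratio),
        chrom = ch, pos = pos,
        group = rep(c("PA", "CN"), each = nr),
        methylated = cbind(ga$meth, gb$meth),
        total = cbind(ga$tot, gb$tot))
    colnames(me) <- c(paste0("PA", seq_len(nr)), paste0("CN", seq_len(nr)))

    ## genomic DNA allele depths
    s <- config@snps
    gdna <- rna <- NULL
    if (nrow(s)) {
        rows <- list()
        for (j in seq_along(config@individuals)) {
            for (i in seq_len(nrow(s))) {
                al <- .splitGenotype(config@genotypes[i, j])
                depth <- rpois(1, config@gdnaDepthMean)
                refN <- if (al[1] != al[2]) rbinom(1, depth, 0.5)
                        else if (al[1] == s$ref[i]) depth else 0L
                rows[[length(rows) + 1L]] <- data.frame(
                    chrom = ch, pos = s$pos[i], ref = s$ref[i], alt = s$alt[i],
                    rsId = s$rsId[i], sampleId = config@individuals[j],
                    source = "gDNA", tissue = NA_character_,
                    refCount = refN, altCount = depth - refN, otherCount = 0L)
            }
        }
        gdna <- alleleCountSet(do.call(rbind, rows))

        ## RNA allele depths, phase-consistent with the paternal haplotype
        inUnit <- s$pos >= config@transcriptUnit[1] &
                  s$pos <= config@transcriptUnit[2]
        meanPat <- (1 + config@purity) / 2
        rows <- list()
        for (j in seq_along(config@individuals)) {
            for (tis in config@tissues) {
                mode <- if (tis %in% names(config@tissueModes))
                    config@tissueModes[[tis]] else config@expressionMode
                for (i in seq_len(nrow(s))) {
                    if (!inUnit[i]) next
                    al <- .splitGenotype(config@genotypes[i, j])
                    if (mode == "silent") { refN <- 0L; depth <- 0L }
                    else {
                        depth <- rpois(1, config@rnaDepthMean)
                        if (al[1] == al[2]) {
                            refN <- if (al[1] == s$ref[i]) depth else 0L
                        } else {
                            expressedFrac <- switch(mode,
                                monoallelic_paternal = .rbetaMean(1, meanPat,
                                    config@overdispersion),
                                monoallelic_maternal = 1 - .rbetaMean(1, meanPat,
                                    config@overdispersion),
                                biallelic = .rbetaMean(1, 0.5,
                                    config@overdispersion))
                            patN <- rbinom(1, depth, expressedFrac)
                            refN <- if (al[2] == s$ref[i]) patN else depth - patN
                        }
                    }
                    rows[[length(rows) + 1L]] <- data.frame(
                        chrom = ch, pos = s$pos[i], ref = s$ref[i],
                        alt = s$alt[i], rsId = s$rsId[i],
                        sampleId = config@individuals[j],
                        source = "RNA", tissue = tis,
                        refCount = refN, altCount = depth - refN,
                        otherCount = 0L)
                }
            }
        }
        rna <- if (length(rows)) alleleCountSet(do.call(rbind, rows)) else NULL
    }
    emptyCounts <- alleleCountSet(data.frame(
        chrom = character(), pos = numeric(), ref = character(),
        alt = character(), rsId = character(), sampleId = character(),
        source = character(), tissue = character(),
        refCount = integer(), altCount = integer(), otherCount = integer()))
    if (is.null(gdna)) gdna <- emptyCounts
    if (is.null(rna)) rna <- emptyCounts

    ## ChIP coverage tracks
    nbin <- max(1L, floor((span[2] - span[1] + 1) / config@binSize))
    mids <- span[1] + (seq_len(nbin) - 1) * config@binSize +
        config@binSize %/% 2
    bump <- rep(0, nbin)
    sigma <- config@peakWidth / 2
    for (cen in config@ctcfPeakCenters)
        bump <- bump + exp(-(mids - cen)^2 / (2 * sigma^2))
    inputTrack <- binnedTrack(rpois(nbin, config@chipNoiseMean),
                              ch, span[1], config@binSize)
    precipTrack <- binnedTrack(
        rpois(nbin, config@chipNoiseMean * (1 + (config@peakFold - 1) * bump)),
        ch, span[1], config@binSize)

    ## precipitate allele counts: CTCF binds both alleles at het sites
    precip <- emptyCounts
    if (nrow(s)) {
        rows <- list()
        for (pef in c("PEF1", "PEF2")) {
            for (i in seq_len(nrow(s))) {
                depth <- rpois(1, config@precipDepthMean)
                refN <- rbinom(1, depth,
                               .rbetaMean(1, 0.5, config@overdispersion))
                rows[[length(rows) + 1L]] <- data.frame(
                    chrom = ch, pos = s$pos[i], ref = s$ref[i], alt = s$alt[i],
                    rsId = s$rsId[i], sampleId = pef, source = "ChIP",
                    tissue = NA_character_, refCount = refN,
                    altCount = depth - refN, otherCount = 0L)
            }
        }
        precip <- alleleCountSet(do.call(rbind, rows))
    }

    ## locus sequence: CpG-depleted background, one planted CpG-rich segment
    n <- span[2] - span[1] + 1
    chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3))
    isCG <- which(chars[-n] == "C" & chars[-1] == "G")
    kill <- isCG[stats::runif(length(isCG)) < 0.8]
    chars[kill + 1L] <- "A"
    if (length(config@islandInterval)) {
        i0 <- config@islandInterval[1] - span[1] + 1
        i1 <- config@islandInterval[2] - span[1] + 1
        chars[i0:i1] <- sample(c("A", "C", "G", "T"), i1 - i0 + 1,
                               replace = TRUE,
                               prob = c(0.17, 0.33, 0.33, 0.17))
    }
    seqn <- DNAString(paste(chars, collapse = ""))

    new("LocusSimulation", methylome = me, gdnaCounts = gdna,
        rnaCounts = rna, precipCounts = precip,
        chipInput = inputTrack, chipPrecip = precipTrack,
        sequence = seqn, truth = config)
}

#' Simulate a null locus (no differential methylation)
#'
#' Identical to [simulateLocus()] except that no DMR intervals are applied:
#' both groups are drawn from the same background distribution. Used for
#' type-I-error calibration of the DMR caller.
#'
#' @param config a \linkS4class{LocusConfig}; its \code{dmrs} are ignored.
#' @return a \linkS4class{LocusSimulation} whose truth carries no DMRs.
#' @export
simulateNullMethylomes <- function(config) {
    stopifnot(is(config, "LocusConfig"))
    cfg <- config
    cfg@dmrs <- data.frame(start = numeric(), end = numeric(),
                           meanA = numeric(), meanB = numeric(),
                           cpgPerKb = numeric())
    simulateLocus(cfg)
}

#' Accessors for LocusSimulation components
#'
#' @param sim a \linkS4class{LocusSimulation}.
#' @return the respective component.
#' @name simulation-accessors
NULL

#' @rdname simulation-accessors
#' @export
methylome <- function(sim) sim@methylome
#' @rdname simulation-accessors
#' @export
gdnaCounts <- function(sim) sim@gdnaCounts
#' @rdname simulation-accessors
#' @export
rnaCounts <- function(sim) sim@rnaCounts
#' @rdname simulation-accessors
#' @export
precipCounts <- function(sim) sim@precipCounts
#' @rdname simulation-accessors
#' @export
chipInput <- function(sim) sim@chipInput
#' @rdname simulation-accessors
#' @export
chipPrecip <- function(sim) sim@chipPrecip
#' @rdname simulation-accessors
#' @export
locusSequence <- function(sim) sim@sequence
#' @rdname simulation-accessors
#' @export
simTruth <- function(sim) sim@truth

#' Paternal allele of each individual at each SNP
#'
#' @param config a \linkS4class{LocusConfig}.
#' @return character matrix (SNPs x individuals) of paternal alleles.
#' @export
paternalAlleles <- function(config) {
    stopifnot(is(config, "LocusConfig"))
    apply(config@genotypes, c(1, 2),
          function(g) .splitGenotype(g)[2])
}
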