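options(imprintKit.logLevel = "quiet")

# O(n^2) brute-force reference for candidate-region segmentation: every
# window over the flagged-CpG list that is same-sign, gap-valid and maximal.
bruteForceCandidates <- function(pos, flags, maxGap = 300, minCpgs = 10) {
    f <- which(flags != 0L)
    res <- list()
    ok <- function(a, b) {
        i <- f[a:b]
        length(unique(flags[i])) == 1L &&
            (length(i) < 2L || all(diff(pos[i]) < maxGap))
    }
    for (a in seq_along(f)) for (b in a:length(f)) {
        if (!ok(a, b)) next
        if (a > 1L && ok(a - 1L, b)) next       # extendable left
        if (b < length(f) && ok(a, b + 1L)) next # extendable right
        if (b - a + 1L < minCpgs) next
        res[[length(res) + 1L]] <- c(pos[f[a]], pos[f[b]], b - a + 1L)
    }
    if (!length(res))
        return(data.frame(start = numeric(), end = numeric(),
                          nDmCpgs = integer()))
    m <- do.call(rbind, res)
    out <- data.frame(start = m[, 1], end = m[, 2], nDmCpgs = as.integer(m[, 3]))
    unique(out[order(out$start), , drop = FALSE])
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n+m, n) rank assignments (no ties assumed)
mannWhitneyEnumP <- function(a, b) {
    n <- length(a); m <- length(b)
    r <- rank(c(a, b))
    u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    combs <- utils::combn(n + m, n)
    us <- apply(combs, 2, function(i) sum(i) - n * (n + 1) / 2)
    min(1, 2 * min(mean(us <= u), mean(us >= u)))
}

# two-sided binomial p vs p0 by summation of all pmf values not exceeding
# the observed one
binomEnumP <- function(k, n, p0 = 0.5) {
    d <- stats::dbinom(0:n, n, p0)
    sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up in one line
bhStepUp <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(q, 1)[order(o)]
}

# MethylomeExperiment whose per-CpG group means are exactly the given
# vectors (each replicate set to the site mean)
meFromMeans <- function(meansA, meansB, nrep = 3, spacing = 50) {
    k <- length(meansA)
    methylomeExperiment(
        ratios = cbind(matrix(rep(meansA, nrep), k),
                       matrix(rep(meansB, nrep), k)),
        chrom = "chr1", pos = seq(100, by = spacing, length.out = k),
        group = rep(c("PA", "CN"), each = nrep))
}

# small, fast locus configuration for boundary/track tests
trackTestConfig <- function(...) {
    locusConfig(locusStart = 1, locusEnd = 60000, cpgPerKb = 2,
                dmrs = NULL, snps = NULL, genotypes = NULL,
                islandInterval = NULL,
                ctcfPeakCenters = c(3000, 55000),
                transcriptUnit = c(10000, 40000), ...)
}
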