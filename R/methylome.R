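#' @importFrom stats wilcox.test p.adjust median rbeta rbinom rpois
NULL

.rowGroupMeans <- function(me) {
    a <- groupRatios(me, "A")
    b <- groupRatios(me, "B")
    list(a = rowMeans(a, na.rm = TRUE), b = rowMeans(b, na.rm = TRUE),
         nA = rowSums(!is.na(a)), nB = rowSums(!is.na(b)))
}

#' Per-CpG methylation difference between groups
#'
#' For every site, the difference of group-mean methylation ratios,
#' group A (maternal-duplicate) minus group B (biparental): the per-site
#' delta-average used to flag differentially methylated CpGs. Sites with
#' fewer than two usable replicate values in either group get \code{NA}.
#'
#' @param me a \linkS4class{MethylomeExperiment}.
#' @return numeric vector in [-1, 1] (or \code{NA}), one value per site.
#' @export
setGeneric("siteDelta", function(me) standardGeneric("siteDelta"))

#' @rdname siteDelta
#' @export
setMethod("siteDelta", "MethylomeExperiment", function(me) {
    if (ncol(groupRatios(me, "A")) == 0L || ncol(groupRatios(me, "B")) == 0L)
        stop("both groups must have at least one replicate")
    gm <- .rowGroupMeans(me)
    d <- gm$a - gm$b
    d[gm$nA < 2L | gm$nB < 2L] <- NA_real_
    unname(d)
})

#' Flag differentially methylated CpGs
#'
#' A CpG is differentially methylated when the absolute per-site delta of
#' group-mean ratios strictly exceeds \code{minDelta}; the sign of the delta
#' is kept so runs of flagged CpGs can be required to share a direction.
#'
#' @param deltas per-site deltas from [siteDelta()].
#' @param minDelta flagging threshold on \code{|delta|}; strict inequality.
#' @return integer vector of signs: +1 (hypermethylated in group A),
#'   -1 (hypomethylated), 0 (not flagged or \code{NA} delta).
#' @export
flagDmCpgs <- function(deltas, minDelta = 0.2) {
    stopifnot(minDelta > 0, minDelta < 1)
    s <- ifelse(!is.na(deltas) & abs(deltas) > minDelta, sign(deltas), 0L)
    as.integer(s)
}

#' Segment flagged CpGs into candidate regions
#'
#' Candidate regions are maximal runs of same-sign flagged CpGs in which
#' every pair of consecutive flagged CpGs is strictly less than
#' \code{maxGap} bp apart. Unflagged CpGs between flagged ones do not break
#' a run (the gap rule applies to the flagged CpGs themselves). Runs with at
#' least \code{minCpgs} flagged CpGs are returned, bounded by their first and
#' last flagged CpG.
#'
#' @param pos sorted 1-based CpG positions.
#' @param flags signed flags from [flagDmCpgs()], parallel to \code{pos}.
#' @param maxGap maximum distance between consecutive flagged CpGs (strict).
#' @param minCpgs minimum number of flagged CpGs per emitted region.
#' @return data.frame with columns \code{start}, \code{end}, \code{nDmCpgs},
#'   \code{sign} and a list column \code{siteIdx} of flagged site indices.
#' @export
segmentCandidates <- function(pos, flags, maxGap = 300, minCpgs = 10) {
    if (is.unsorted(pos)) stop("positions must be sorted")
    stopifnot(length(pos) == length(flags), maxGap > 0, minCpgs >= 1)
    idx <- which(flags != 0L)
    out <- data.frame(start = numeric(), end = numeric(),
                      nDmCpgs = integer(), sign = integer())
    out$siteIdx <- list()
    if (!length(idx)) return(out)
    p <- pos[idx]; s <- flags[idx]
    newRun <- c(TRUE, diff(p) >= maxGap | diff(s) != 0L)
    run <- cumsum(newRun)
    keep <- which(tabulate(run) >= minCpgs)
    if (!length(keep)) return(out)
    res <- lapply(keep, function(k) {
        i <- idx[run == k]
        list(start = pos[i[1L]], end = pos[i[length(i)]],
             n = length(i), sign = flags[i[1L]], idx = i)
    })
    out <- data.frame(start = vapply(res, `[[`, numeric(1), "start"),
                      end = vapply(res, `[[`, numeric(1), "end"),
                      nDmCpgs = vapply(res, `[[`, integer(1), "n"),
                      sign = vapply(res, `[[`, integer(1), "sign"))
    out$siteIdx <- lapply(res, `[[`, "idx")
    out[order(out$start), , drop = FALSE]
}

.regionTest <- function(a, b) {
    # Mann-Whitney U on per-CpG group means; exact null for <= 12 per side
    # (requires no ties), normal approximation otherwise.
    if (stats::var(c(a, b)) == 0) return(1)
    exact <- length(a) <= 12L && length(b) <= 12L &&
        !anyDuplicated(c(a, b))
    suppressWarnings(
        wilcox.test(a, b, alternative = "two.sided", exact = exact,
                    correct = TRUE)$p.value)
}

#' Test candidate regions and adjust for multiple testing
#'
#' Each candidate is scored with a two-sided Mann-Whitney U test comparing
#' the per-CpG group-mean methylation values of the two groups across the
#' region's flagged CpGs (exact null when both sides have at most 12 CpGs and
#' no ties, normal approximation otherwise). Benjamini-Hochberg adjustment is
#' applied across all candidates of the call.
#'
#' @param candidates data.frame from [segmentCandidates()].
#' @param me the \linkS4class{MethylomeExperiment} the candidates index into.
#' @return \code{candidates} with added \code{deltaAve}, \code{pValue} and
#'   \code{qValue} columns.
#' @export
testRegions <- function(candidates, me) {
    gm <- .rowGroupMeans(me)
    n <- nrow(candidates)
    p <- numeric(n); dav <- numeric(n)
    for (i in seq_len(n)) {
        ii <- candidates$siteIdx[[i]]
        if (length(ii) < 2L) stop("candidates must hold at least 2 CpGs")
        a <- gm$a[ii]; b <- gm$b[ii]
        dav[i] <- mean(a) - mean(b)
        p[i] <- .regionTest(a, b)
    }
    candidates$deltaAve <- dav
    candidates$pValue <- p
    candidates$qValue <- p.adjust(p, method = "BH")
    candidates
}

#' Call differentially methylated regions
#'
#' Composes per-site delta flagging, same-sign run segmentation, the
#' region-level Mann-Whitney test and Benjamini-Hochberg adjustment, then
#' emits regions that hold at least \code{minCpgs} flagged CpGs, satisfy
#' \code{|deltaAve| > minDelta} at the region level, and reach
#' \code{qValue < fdr}. Direction is \code{"maternal_hyper"} when the
#' maternal-duplicate group A is the more methylated one.
#'
#' Sites with fewer than two usable replicate values in either group are
#' dropped before flagging (they never break a run, since the gap rule binds
#' flagged CpGs only).
#'
#' @param me a \linkS4class{MethylomeExperiment}.
#' @param minDelta per-site and region \code{|delta|} threshold (strict).
#' @param maxGap maximum distance between consecutive flagged CpGs (strict).
#' @param minCpgs minimum flagged CpGs per region.
#' @param fdr Benjamini-Hochberg threshold (strict).
#' @return a \code{GRanges} (1-based inclusive bounds at the first and last
#'   flagged CpG) with mcols \code{nDmCpgs}, \code{deltaAve}, \code{pValue},
#'   \code{qValue}, \code{direction}.
#' @examples
#' cfg <- locusConfig(seed = 7)
#' sim <- simulateLocus(cfg)
#' callDmrs(methylome(sim))
#' @export
setGeneric("callDmrs", function(me, minDelta = 0.2, maxGap = 300,
                                minCpgs = 10, fdr = 0.05)
    standardGeneric("callDmrs"))

#' @rdname callDmrs
#' @export
setMethod("callDmrs", "MethylomeExperiment",
          function(me, minDelta = 0.2, maxGap = 300, minCpgs = 10, fdr = 0.05) {
    .log("callDmrs: %d sites, minDelta=%g maxGap=%g minCpgs=%d fdr=%g",
         nrow(me), minDelta, maxGap, minCpgs, fdr)
    empty <- GRanges(seqnames = character(),
                     ranges = IRanges(),
                     nDmCpgs = integer(), deltaAve = numeric(),
                     pValue = numeric(), qValue = numeric(),
                     direction = character())
    if (!nrow(me)) return(empty)
    gm <- .rowGroupMeans(me)
    usable <- gm$nA >= 2L & gm$nB >= 2L
    me <- me[usable, ]
    if (!nrow(me)) return(empty)
    rr <- SummarizedExperiment::rowRanges(me)
    flags <- flagDmCpgs(siteDelta(me), minDelta)
    cands <- NULL
    for (ch in unique(as.character(seqnames(rr)))) {
        onCh <- which(as.character(seqnames(rr)) == ch)
        cc <- segmentCandidates(start(rr)[onCh], flags[onCh],
                                maxGap = maxGap, minCpgs = minCpgs)
        if (nrow(cc)) {
            cc$chrom <- ch
            cc$siteIdx <- lapply(cc$siteIdx, function(i) onCh[i])
            cands <- if (is.null(cands)) cc else rbind(cands, cc)
        }
    }
    if (is.null(cands) || !nrow(cands)) return(empty)
    cands <- testRegions(cands, me)
    keep <- cands$qValue < fdr & abs(cands$deltaAve) > minDelta
    cands <- cands[keep, , drop = FALSE]
    .log("callDmrs: %d candidate(s), %d emitted", length(keep), nrow(cands))
    if (!nrow(cands)) return(empty)
    GRanges(cands$chrom, IRanges(cands$start, cands$end),
            nDmCpgs = cands$nDmCpgs, deltaAve = cands$deltaAve,
            pValue = cands$pValue, qValue = cands$qValue,
            direction = ifelse(cands$deltaAve > 0,
                               "maternal_hyper", "maternal_hypo"))
})
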