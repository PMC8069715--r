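#' Construct a MethylomeExperiment
#'
#' @param ratios numeric matrix of methylation ratios, sites x replicates.
#' @param chrom chromosome name (recycled) or vector.
#' @param pos 1-based CpG cytosine positions (plus strand), one per row.
#' @param group group label per column; the first distinct label becomes
#'   group A, the maternal-duplicate (parthenogenetic) group.
#' @param methylated,total optional count matrices matching \code{ratios}.
#'
#' @return a \linkS4class{MethylomeExperiment} with rows sorted by position.
#' @examples
#' me <- methylomeExperiment(
#'     ratios = cbind(a1 = c(0.9, 0.8), a2 = c(1, 0.9),
#'                    b1 = c(0.4, 0.5), b2 = c(0.5, 0.4)),
#'     chrom = "chr1", pos = c(100, 160),
#'     group = c("PA", "PA", "CN", "CN"))
#' siteDelta(me)
#' @export
methylomeExperiment <- function(ratios, chrom, pos, group,
                                methylated = NULL, total = NULL) {
    ratios <- as.matrix(ratios)
    if (length(pos) != nrow(ratios))
        stop("'pos' must have one entry per row of 'ratios'")
    if (length(group) != ncol(ratios))
        stop("'group' must have one entry per column of 'ratios'")
    rr <- GRanges(rep(chrom, length.out = length(pos)),
                  IRanges(pos, width = 1L))
    o <- order(as.character(seqnames(rr)), start(rr))
    assays <- list(ratio = ratios[o, , drop = FALSE])
    if (!is.null(methylated)) assays$methylated <- as.matrix(methylated)[o, , drop = FALSE]
    if (!is.null(total)) assays$total <- as.matrix(total)[o, , drop = FALSE]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, rowRanges = rr[o],
        colData = DataFrame(group = factor(group, levels = unique(group))))
    new("MethylomeExperiment", se)
}

#' Construct an AlleleCountSet
#'
#' @param x a data.frame or DataFrame with the columns documented in
#'   \linkS4class{AlleleCountSet} (missing \code{rsId}, \code{tissue} and
#'   \code{otherCount} are filled with \code{NA}/0).
#' @return an \linkS4class{AlleleCountSet}.
#' @export
alleleCountSet <- function(x) {
    x <- as(as.data.frame(x), "DataFrame")
    if (!"rsId" %in% colnames(x)) x$rsId <- rep(NA_character_, nrow(x))
    if (!"tissue" %in% colnames(x)) x$tissue <- rep(NA_character_, nrow(x))
    if (!"otherCount" %in% colnames(x)) x$otherCount <- rep(0L, nrow(x))
    x$refCount <- as.integer(x$refCount)
    x$altCount <- as.integer(x$altCount)
    x$otherCount <- as.integer(x$otherCount)
    new("AlleleCountSet", x[, .alleleCountCols])
}

#' Construct a BinnedTrack
#'
#' @param values per-bin coverage values.
#' @param chrom chromosome name.
#' @param start 1-based coordinate of the first bin's first base.
#' @param binSize bin width in bp.
#' @return a \linkS4class{BinnedTrack}.
#' @export
binnedTrack <- function(values, chrom = "chr1", start = 1, binSize = 200) {
    new("BinnedTrack", chrom = chrom, start = as.numeric(start),
        binSize = as.numeric(binSize), values = as.numeric(values))
}

#' Genomic midpoints of the bins of a track
#'
#' @param track a \linkS4class{BinnedTrack}.
#' @return numeric vector of bin midpoint coordinates.
#' @export
binMidpoints <- function(track) {
    stopifnot(is(track, "BinnedTrack"))
    track@start + (seq_along(track@values) - 1L) * track@binSize +
        track@binSize %/% 2
}

#' Convert a BinnedTrack to a GRanges with a score column
#'
#' @param track a \linkS4class{BinnedTrack}.
#' @return a \code{GRanges} with one range per bin and \code{score} mcol.
#' @export
trackAsGRanges <- function(track) {
    stopifnot(is(track, "BinnedTrack"))
    n <- length(track@values)
    gr <- GRanges(track@chrom,
                  IRanges(start = track@start + (seq_len(n) - 1L) * track@binSize,
                          width = track@binSize))
    gr$score <- track@values
    gr
}

#' Build a BinnedTrack from a GRanges of equal-width bins
#'
#' @param gr a \code{GRanges} with a numeric \code{score} column and
#'   equal-width, contiguous or sorted bins on one chromosome.
#' @return a \linkS4class{BinnedTrack}.
#' @export
grangesAsTrack <- function(gr) {
    if (length(unique(as.character(seqnames(gr)))) != 1L)
        stop("track must cover a single chromosome")
    gr <- GenomicRanges::sort(gr)
    w <- unique(width(gr))
    if (length(w) != 1L)
        stop("bins must have equal width")
    binnedTrack(gr$score, chrom = as.character(seqnames(gr))[1],
                start = start(gr)[1], binSize = w)
}

#' Group labels of a MethylomeExperiment
#'
#' @param x a \linkS4class{MethylomeExperiment}.
#' @return the two group levels; the first is the maternal-duplicate group.
#' @export
groupLevels <- function(x) {
    stopifnot(is(x, "MethylomeExperiment"))
    levels(SummarizedExperiment::colData(x)$group)
}

#' Methylation ratio matrix of one group
#'
#' @param x a \linkS4class{MethylomeExperiment}.
#' @param group \code{"A"} (maternal-duplicate) or \code{"B"} (biparental),
#'   or an explicit group label.
#' @return the sites x replicates ratio matrix of that group.
#' @export
groupRatios <- function(x, group = c("A", "B")) {
    stopifnot(is(x, "MethylomeExperiment"))
    lv <- groupLevels(x)
    if (group[1] %in% c("A", "B"))
        group <- lv[match(group[1], c("A", "B"))]
    else group <- match.arg(group, lv)
    g <- SummarizedExperiment::colData(x)$group
    SummarizedExperiment::assay(x, "ratio")[, g == group, drop = FALSE]
}
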