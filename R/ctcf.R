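#' Detect CTCF-enriched regions on a coverage track
#'
#' Background is the median bin value with a floor of one unit (so empty
#' tracks cannot yield a zero background); enriched regions are maximal runs
#' of bins with coverage at least \code{minFold} times background. Runs
#' separated by fewer than two below-threshold bins are merged, and merged
#' runs narrower than \code{minWidth} are dropped. Because the threshold is
#' relative to background, scaling a whole track by a positive constant
#' leaves the peak set unchanged (as long as the background stays above the
#' unit floor).
#'
#' @param track a \linkS4class{BinnedTrack}.
#' @param minFold enrichment threshold over background (> 1).
#' @param minWidth minimum peak width in bp (>= one bin).
#' @return a \code{GRanges} of peaks with mcols \code{apex} (coordinate of
#'   the maximum bin's midpoint) and \code{foldEnrichment} (apex value over
#'   background).
#' @examples
#' tr <- binnedTrack(c(rep(10, 20), rep(120, 5), rep(10, 20)))
#' detectEnrichedRegions(tr)
#' @export
detectEnrichedRegions <- function(track, minFold = 5, minWidth = 200) {
    stopifnot(is(track, "BinnedTrack"), minFold > 1,
              minWidth >= track@binSize)
    v <- track@values
    empty <- GRanges(seqnames = character(), ranges = IRanges(),
                     apex = numeric(), foldEnrichment = numeric())
    if (!length(v) || all(v == 0)) return(empty)
    bg <- max(median(v), 1)
    above <- v >= minFold * bg
    if (!any(above)) return(empty)
    r <- rle(above)
    # merge runs separated by a single below-threshold bin
    gap1 <- which(!r$values & r$lengths < 2L)
    gap1 <- gap1[gap1 > 1L & gap1 < length(r$values)]
    r$values[gap1] <- TRUE
    above <- inverse.rle(r)
    r <- rle(above)
    endBin <- cumsum(r$lengths)
    startBin <- endBin - r$lengths + 1L
    keep <- r$values & r$lengths * track@binSize >= minWidth
    if (!any(keep)) return(empty)
    startBin <- startBin[keep]; endBin <- endBin[keep]
    mids <- binMidpoints(track)
    peaks <- lapply(seq_along(startBin), function(i) {
        bins <- startBin[i]:endBin[i]
        apexBin <- bins[which.max(v[bins])]
        list(start = track@start + (startBin[i] - 1L) * track@binSize,
             end = track@start + endBin[i] * track@binSize - 1L,
             apex = mids[apexBin], fold = v[apexBin] / bg)
    })
    .log("detectEnrichedRegions: %d peak(s), background %g", length(peaks), bg)
    GRanges(track@chrom,
            IRanges(vapply(peaks, `[[`, numeric(1), "start"),
                    vapply(peaks, `[[`, numeric(1), "end")),
            apex = vapply(peaks, `[[`, numeric(1), "apex"),
            foldEnrichment = vapply(peaks, `[[`, numeric(1), "fold"))
}

#' Boundary pair flanking a transcription unit
#'
#' Selects the nearest enriched region on each side of the transcription
#' unit - entirely upstream of the unit start, and downstream of (or
#' overlapping) the unit end - and measures the boundary gap apex-to-apex,
#' the only unambiguous single number for an approximate boundary distance.
#'
#' @param peaks a \code{GRanges} from [detectEnrichedRegions()].
#' @param unit a length-1 \code{GRanges} (or \code{c(start, end)} vector)
#'   delimiting the transcription unit.
#' @return a list (class \code{"boundaryPair"}) with \code{upstream},
#'   \code{downstream} (single-peak \code{GRanges}) and \code{gapBp}.
#' @export
flankingBoundaryGap <- function(peaks, unit) {
    if (is.numeric(unit)) {
        stopifnot(length(unit) == 2L)
        us <- unit[1]; ue <- unit[2]
    } else {
        stopifnot(is(unit, "GRanges"), length(unit) == 1L)
        us <- start(unit); ue <- end(unit)
    }
    upIdx <- which(end(peaks) < us)
    downIdx <- which(start(peaks) > ue |
                     (end(peaks) >= ue & peaks$apex > ue))
    if (!length(upIdx)) stop("no upstream boundary")
    if (!length(downIdx)) stop("no downstream boundary")
    up <- upIdx[which.max(peaks$apex[upIdx])]
    down <- downIdx[which.min(peaks$apex[downIdx])]
    gap <- peaks$apex[down] - peaks$apex[up]
    stopifnot(gap > 0)
    structure(list(upstream = peaks[up], downstream = peaks[down],
                   gapBp = gap),
              class = "boundaryPair")
}

#' @export
print.boundaryPair <- function(x, ...) {
    cat(sprintf("boundary pair: apexes %d .. %d, gap %d bp\n",
                as.integer(x$upstream$apex), as.integer(x$downstream$apex),
                as.integer(x$gapBp)))
    invisible(x)
}

#' Classify ChIP precipitate allele counts
#'
#' Tests whether CTCF precipitates both alleles at a heterozygous site:
#' \code{"biallelic"} when depth reaches \code{minDepth} and both allele
#' fractions are at least \code{minAlleleFrac}; \code{"allele_specific"}
#' when depth suffices but the minor fraction is below 0.05;
#' \code{"inconclusive"} otherwise (including sites without a heterozygous
#' input allele, which are untestable rather than biallelic). When the input
#' allele fractions are supplied, a two-sided binomial p-value of the
#' precipitate counts against the input reference fraction is reported as an
#' enrichment-shift note.
#'
#' @param refCount,altCount precipitate read counts for the two alleles.
#' @param inputFracs optional \code{c(ref, alt)} fractions observed in the
#'   input (chromatin before precipitation).
#' @param minAlleleFrac minimum fraction of each allele for a biallelic call.
#' @param minDepth minimum precipitate depth.
#' @return a list with \code{call}, \code{percentRef}, \code{percentAlt},
#'   \code{minorFraction} and \code{pVsInput} (\code{NA} without input
#'   fractions).
#' @examples
#' classifyPrecipitation(88, 65, inputFracs = c(0.25, 0.75))
#' @export
classifyPrecipitation <- function(refCount, altCount, inputFracs = NULL,
                                  minAlleleFrac = 0.25, minDepth = 20) {
    total <- refCount + altCount
    if (total == 0)
        return(list(call = "inconclusive", percentRef = NA_integer_,
                    percentAlt = NA_integer_, minorFraction = NA_real_,
                    pVsInput = NA_real_))
    fr <- refCount / total
    minor <- min(fr, 1 - fr)
    call <- if (total >= minDepth && minor >= minAlleleFrac) "biallelic"
            else if (total >= minDepth && minor < 0.05) "allele_specific"
            else "inconclusive"
    p <- NA_real_
    if (!is.null(inputFracs)) {
        stopifnot(length(inputFracs) == 2L,
                  abs(sum(inputFracs) - 1) < 1e-6)
        p <- binom.test(refCount, total, p = inputFracs[1],
                        alternative = "two.sided")$p.value
    }
    list(call = call,
         percentRef = percentRound(100 * fr),
         percentAlt = percentRound(100 * (1 - fr)),
         minorFraction = minor, pVsInput = p)
}
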