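#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet
NULL

.seqChars <- function(seq) {
    s <- if (is(seq, "DNAString") || is(seq, "DNAStringSet"))
        as.character(seq) else as.character(seq[[1]])
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
    if (length(bad))
        stop("sequence contains characters other than A/C/G/T/N: ",
             paste(bad, collapse = ", "))
    chars
}

# cumulative counts supporting O(1) window queries
.seqCums <- function(chars) {
    n <- length(chars)
    cg <- c(chars[-n] == "C" & chars[-1] == "G", FALSE)
    list(C = cumsum(chars == "C"), G = cumsum(chars == "G"),
         N = cumsum(chars == "N"), CG = cumsum(cg), n = n)
}

# stats for windows [s, e]; CG dinucleotides counted when fully inside
.windowStatsAt <- function(cums, s, e) {
    at <- function(v, i) ifelse(i >= 1, v[pmax(i, 1)], 0)
    nC <- at(cums$C, e) - at(cums$C, s - 1)
    nG <- at(cums$G, e) - at(cums$G, s - 1)
    nN <- at(cums$N, e) - at(cums$N, s - 1)
    nCG <- at(cums$CG, e - 1) - at(cums$CG, s - 1)
    len <- e - s + 1 - nN
    gc <- ifelse(len > 0, (nC + nG) / len, 0)
    obsExp <- ifelse(nC > 0 & nG > 0, nCG / (nC * nG / pmax(len, 1)), 0)
    data.frame(start = s, end = e, gc = gc, obsExp = obsExp, nFrac = nN / (e - s + 1))
}

#' GC content and CpG observed/expected in sliding windows
#'
#' Slides windows of \code{window} bp by \code{step} bp across the sequence
#' and reports, per window, the GC fraction and the CpG observed/expected
#' ratio \code{count(CG) / (count(C) * count(G) / length)}. Ns are excluded
#' from both numerator and denominator; windows with more than 50\% N are
#' skipped; a final partial window is included when at least half a window
#' remains. A ratio of 0 is reported when a window has no C or no G.
#'
#' @param seq a \code{DNAString}, \code{DNAStringSet} (first sequence) or
#'   character string over A/C/G/T/N.
#' @param window window width in bp (>= 10).
#' @param step step in bp (>= 1).
#' @return data.frame with \code{start}, \code{end} (1-based inclusive,
#'   relative to the sequence), \code{gc}, \code{obsExp}.
#' @export
windowStats <- function(seq, window = 200, step = 50) {
    stopifnot(window >= 10, step >= 1)
    chars <- .seqChars(seq)
    n <- length(chars)
    if (n < window / 2)
        return(data.frame(start = numeric(), end = numeric(),
                          gc = numeric(), obsExp = numeric()))
    starts <- seq.int(1L, max(n - window + 1L, 1L), by = step)
    ends <- pmin(starts + window - 1L, n)
    # candidate partial tail window
    lastEnd <- ends[length(ends)]
    if (lastEnd < n) {
        s2 <- starts[length(starts)] + step
        if (n - s2 + 1 >= window / 2) {
            starts <- c(starts, s2); ends <- c(ends, n)
        }
    }
    cums <- .seqCums(chars)
    st <- .windowStatsAt(cums, starts, ends)
    st <- st[st$nFrac <= 0.5, c("start", "end", "gc", "obsExp")]
    rownames(st) <- NULL
    st
}

#' Detect CpG islands
#'
#' Applies the classical genome-browser criteria (length >= 200 bp,
#' GC > 50\%, CpG observed/expected > 0.6 by default): all 200-bp windows
#' stepped by 1 that satisfy the GC and observed/expected thresholds are
#' merged when overlapping, and each merged interval is re-checked against
#' the thresholds and the minimum length before being emitted.
#'
#' @param seq sequence as for [windowStats()].
#' @param minLen minimum island length in bp.
#' @param minGc GC-fraction threshold (strict).
#' @param minObsExp CpG observed/expected threshold (strict).
#' @param chrom sequence/chromosome name for the returned ranges.
#' @param offset 0-based genomic offset of the sequence's first base (so
#'   coordinates can be reported on the chromosome).
#' @return a \code{GRanges} of islands with mcols \code{lengthBp},
#'   \code{gc}, \code{obsExp}.
#' @export
findCpgIslands <- function(seq, minLen = 200, minGc = 0.5, minObsExp = 0.6,
                           chrom = "seq", offset = 0) {
    chars <- .seqChars(seq)
    n <- length(chars)
    empty <- GRanges(seqnames = character(), ranges = IRanges(),
                     lengthBp = integer(), gc = numeric(), obsExp = numeric())
    w <- 200L
    if (n < max(minLen, w)) return(empty)
    cums <- .seqCums(chars)
    starts <- seq_len(n - w + 1L)
    st <- .windowStatsAt(cums, starts, starts + w - 1L)
    qual <- st$gc > minGc & st$obsExp > minObsExp & st$nFrac <= 0.5
    if (!any(qual)) return(empty)
    merged <- IRanges::reduce(IRanges(starts[qual], width = w))
    ms <- .windowStatsAt(cums, start(merged), end(merged))
    keep <- width(merged) >= minLen & ms$gc > minGc & ms$obsExp > minObsExp
    if (!any(keep)) return(empty)
    merged <- merged[keep]; ms <- ms[keep, , drop = FALSE]
    GRanges(chrom, IRanges(start(merged) + offset, end(merged) + offset),
            lengthBp = width(merged), gc = ms$gc, obsExp = ms$obsExp)
}

#' Length of a 1-based inclusive interval
#'
#' @param start,end 1-based inclusive bounds (vectorised).
#' @return \code{end - start + 1} in bp.
#' @examples
#' intervalLength(21303765, 21304604) # the 840-bp CpG island
#' @export
intervalLength <- function(start, end) {
    if (any(start > end)) stop("interval start must not exceed end")
    end - start + 1
}
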