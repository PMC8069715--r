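#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom Biostrings DNAString
NULL

.checkInterval <- function(x, what) {
    if (length(x) != 2L || any(is.na(x)) || x[1] > x[2])
        return(sprintf("'%s' must be a (start, end) pair with start <= end", what))
    NULL
}

#' Configuration of a synthetic imprinted locus
#'
#' A \code{LocusConfig} fixes every parameter of the virtual imprinted locus:
#' coordinates, CpG placement, planted DMRs with group-specific methylation
#' means, SNP genotypes with explicit parental phase, the expression mode of
#' the transcription unit, ChIP enrichment geometry, and the seed. The same
#' configuration with the same seed always yields the same simulation.
#'
#' Genotype strings are written \code{"M|P"} (maternal allele, pipe, paternal
#' allele); under monoallelic paternal expression the paternal allele is the
#' expressed one at every heterozygous site of an individual, so simulated RNA
#' counts are phase-consistent by construction.
#'
#' @slot chrom chromosome name.
#' @slot locusStart,locusEnd 1-based inclusive locus bounds (bp).
#' @slot nReplicates methylome replicates per group.
#' @slot backgroundMean background methylation ratio, both groups.
#' @slot betaConcentration beta concentration of per-replicate ratio scatter.
#' @slot coverageMean mean per-CpG bisulfite read depth.
#' @slot cpgPerKb expected CpGs per kb outside planted DMRs.
#' @slot dmrs data.frame with columns \code{start}, \code{end}, \code{meanA}
#'   (maternal-duplicate group), \code{meanB} (biparental group) and optional
#'   \code{cpgPerKb}; intervals must not overlap.
#' @slot snps data.frame with columns \code{pos}, \code{ref}, \code{alt},
#'   \code{rsId} (\code{NA} for unreported sites).
#' @slot individuals individual labels (columns of \code{genotypes}).
#' @slot genotypes character matrix (SNPs x individuals) of \code{"M|P"} pairs.
#' @slot transcriptUnit (start, end) of the transcription unit.
#' @slot expressionMode one of \code{"monoallelic_paternal"},
#'   \code{"biallelic"}, \code{"silent"}.
#' @slot tissueModes named character vector of per-tissue mode overrides.
#' @slot tissues tissue labels for RNA counts.
#' @slot rnaDepthMean,gdnaDepthMean mean allele-count depths.
#' @slot overdispersion beta-binomial concentration of allele fractions.
#' @slot purity guaranteed minimum expected paternal-allele fraction under
#'   monoallelic expression.
#' @slot ctcfPeakCenters genomic positions of planted CTCF peaks.
#' @slot peakFold,peakWidth ChIP enrichment over background and peak width (bp).
#' @slot binSize coverage-track bin size (bp).
#' @slot chipNoiseMean mean background coverage per ChIP-track bin.
#' @slot precipDepthMean mean depth of precipitate allele counts.
#' @slot islandInterval (start, end) of the planted CpG-rich segment, or
#'   numeric(0) for none.
#' @slot seed integer seed.
#'
#' @seealso [locusConfig()], [simulateLocus()]
#' @export
setClass("LocusConfig", representation(
    chrom = "character",
    locusStart = "numeric", locusEnd = "numeric",
    nReplicates = "integer",
    backgroundMean = "numeric", betaConcentration = "numeric",
    coverageMean = "numeric", cpgPerKb = "numeric",
    dmrs = "data.frame",
    snps = "data.frame",
    individuals = "character", genotypes = "matrix",
    transcriptUnit = "numeric", expressionMode = "character",
    tissueModes = "character", tissues = "character",
    rnaDepthMean = "numeric", gdnaDepthMean = "numeric",
    overdispersion = "numeric", purity = "numeric",
    ctcfPeakCenters = "numeric", peakFold = "numeric", peakWidth = "numeric",
    binSize = "numeric", chipNoiseMean = "numeric", precipDepthMean = "numeric",
    islandInterval = "numeric",
    seed = "integer"))

setValidity("LocusConfig", function(object) {
    msg <- character()
    span <- c(object@locusStart, object@locusEnd)
    msg <- c(msg, .checkInterval(span, "locus span"))
    inSpan <- function(x) all(x >= span[1] & x <= span[2])
    d <- object@dmrs
    if (nrow(d)) {
        if (!all(c("start", "end", "meanA", "meanB") %in% names(d)))
            msg <- c(msg, "'dmrs' needs columns start, end, meanA, meanB")
        else {
            if (!inSpan(c(d$start, d$end)) || any(d$start > d$end))
                msg <- c(msg, "dmr intervals must lie within the locus span")
            if (any(c(d$meanA, d$meanB) < 0 | c(d$meanA, d$meanB) > 1))
                msg <- c(msg, "dmr methylation means must be in [0, 1]")
            if (nrow(d) > 1L) {
                o <- order(d$start)
                if (any(d$start[o][-1L] <= d$end[o][-nrow(d)]))
                    msg <- c(msg, "dmr intervals must not overlap")
            }
        }
    }
    if (object@backgroundMean < 0 || object@backgroundMean > 1)
        msg <- c(msg, "'backgroundMean' must be in [0, 1]")
    if (object@purity <= 0 || object@purity > 1)
        msg <- c(msg, "'purity' must be in (0, 1]")
    pos <- c(object@betaConcentration, object@coverageMean,
             object@rnaDepthMean, object@gdnaDepthMean, object@overdispersion,
             object@peakFold, object@peakWidth, object@binSize,
             object@chipNoiseMean, object@precipDepthMean)
    if (any(!is.finite(pos)) || any(pos <= 0))
        msg <- c(msg, "depths, concentrations and track parameters must be positive")
    if (object@cpgPerKb < 0) msg <- c(msg, "'cpgPerKb' must be >= 0")
    s <- object@snps
    if (nrow(s)) {
        if (!inSpan(s$pos))
            msg <- c(msg, "snp positions must lie within the locus span")
        if (any(s$ref == s$alt) ||
            !all(c(s$ref, s$alt) %in% c("A", "C", "G", "T")))
            msg <- c(msg, "snp ref/alt must be distinct bases in {A,C,G,T}")
        if (!identical(dim(object@genotypes),
                       c(nrow(s), length(object@individuals))))
            msg <- c(msg, "'genotypes' must be a SNPs x individuals matrix")
        else {
            for (i in seq_len(nrow(s))) {
                al <- strsplit(object@genotypes[i, ], "|", fixed = TRUE)
                ok <- vapply(al, function(g) length(g) == 2L &&
                    all(g %in% c(s$ref[i], s$alt[i])), logical(1))
                if (!all(ok))
                    msg <- c(msg, sprintf(
                        "genotypes at snp %d must be 'M|P' pairs over {%s,%s}",
                        i, s$ref[i], s$alt[i]))
            }
        }
    }
    if (length(object@transcriptUnit))
        msg <- c(msg, .checkInterval(object@transcriptUnit, "transcriptUnit"))
    if (!object@expressionMode %in% c("monoallelic_paternal", "biallelic", "silent"))
        msg <- c(msg, "unknown 'expressionMode'")
    if (length(object@tissueModes) &&
        !all(object@tissueModes %in% c("monoallelic_paternal", "monoallelic_maternal",
                                       "biallelic", "silent")))
        msg <- c(msg, "unknown mode in 'tissueModes'")
    if (length(object@islandInterval))
        msg <- c(msg, .checkInterval(object@islandInterval, "islandInterval"))
    if (length(object@ctcfPeakCenters) && !inSpan(object@ctcfPeakCenters))
        msg <- c(msg, "ctcf peak centers must lie within the locus span")
    if (length(msg)) msg else TRUE
})

#' Two-group methylome container
#'
#' A \code{MethylomeExperiment} is a \linkS4class{RangedSummarizedExperiment}
#' holding one row per CpG site (width-1 ranges at the plus-strand cytosine)
#' and one column per replicate. The \code{"ratio"} assay stores methylation
#' ratios in [0, 1]; optional \code{"methylated"} and \code{"total"} assays
#' store the underlying counts. \code{colData(x)$group} is a two-level factor
#' whose first level is group A, the maternal-duplicate (parthenogenetic)
#' group; group B holds the biparental controls.
#'
#' @seealso [methylomeExperiment()], [callDmrs()], [siteDelta()]
#' @export
setClass("MethylomeExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("MethylomeExperiment", function(object) {
    msg <- character()
    if (!"ratio" %in% SummarizedExperiment::assayNames(object))
        return("assay 'ratio' is required")
    r <- SummarizedExperiment::assay(object, "ratio")
    if (any(r < 0 | r > 1, na.rm = TRUE))
        msg <- c(msg, "methylation ratios must be in [0, 1]")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% names(cd) || !is.factor(cd$group) ||
        nlevels(cd$group) != 2L)
        msg <- c(msg, "colData must have a two-level factor 'group'")
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr) && any(width(rr) != 1L))
        msg <- c(msg, "sites must be width-1 ranges (CpG cytosine positions)")
    if (length(msg)) msg else TRUE
})

#' Table of per-sample allele depths
#'
#' An \code{AlleleCountSet} is a \linkS4class{DataFrame} with one row per
#' (site, sample, tissue) allele-depth record and the fixed columns
#' \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt}, \code{rsId}
#' (\code{NA} when unreported), \code{sampleId}, \code{source} (\code{"gDNA"}
#' or \code{"RNA"}), \code{tissue} (\code{NA} for gDNA and ChIP input),
#' \code{refCount}, \code{altCount}, \code{otherCount} (reads matching
#' neither configured allele).
#'
#' @seealso [alleleCountSet()], [classifyGenotype()],
#'   [classifyAllelicExpression()]
#' @export
setClass("AlleleCountSet", contains = "DFrame")

.alleleCountCols <- c("chrom", "pos", "ref", "alt", "rsId", "sampleId",
                      "source", "tissue", "refCount", "altCount", "otherCount")

setValidity("AlleleCountSet", function(object) {
    msg <- character()
    missing <- setdiff(.alleleCountCols, colnames(object))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    cnt <- cbind(object$refCount, object$altCount, object$otherCount)
    if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "counts must be non-negative integers")
    if (!all(object$source %in% c("gDNA", "RNA", "ChIP")))
        msg <- c(msg, "source must be one of gDNA, RNA, ChIP")
    if (length(msg)) msg else TRUE
})

#' Binned genomic coverage track
#'
#' Holds normalized per-bin coverage for one chromosome as equal-width bins:
#' bin i covers \code{start + (i-1)*binSize} to \code{start + i*binSize - 1}
#' (1-based inclusive).
#'
#' @slot chrom chromosome name.
#' @slot start 1-based coordinate of the first bin's first base.
#' @slot binSize bin width in bp.
#' @slot values ordered non-negative per-bin coverage.
#'
#' @seealso [binnedTrack()], [detectEnrichedRegions()]
#' @export
setClass("BinnedTrack", representation(
    chrom = "character", start = "numeric",
    binSize = "numeric", values = "numeric"))

setValidity("BinnedTrack", function(object) {
    msg <- character()
    if (object@binSize < 1) msg <- c(msg, "'binSize' must be >= 1")
    if (any(!is.finite(object@values)) || any(object@values < 0))
        msg <- c(msg, "track values must be finite and non-negative")
    if (length(msg)) msg else TRUE
})

#' A simulated imprinted-locus bundle
#'
#' The full output of [simulateLocus()]: methylomes for both groups, genomic
#' DNA and per-tissue RNA allele depths, ChIP input and precipitate coverage
#' tracks, precipitate allele counts, the locus DNA sequence with its planted
#' CpG-rich segment, and the generating \linkS4class{LocusConfig} as ground
#' truth.
#'
#' @slot methylome a \linkS4class{MethylomeExperiment}.
#' @slot gdnaCounts,rnaCounts,precipCounts \linkS4class{AlleleCountSet}s.
#' @slot chipInput,chipPrecip \linkS4class{BinnedTrack}s.
#' @slot sequence a \linkS4class{DNAString} spanning the locus.
#' @slot truth the \linkS4class{LocusConfig} used.
#' @export
setClass("LocusSimulation", representation(
    methylome = "MethylomeExperiment",
    gdnaCounts = "AlleleCountSet",
    rnaCounts = "AlleleCountSet",
    precipCounts = "AlleleCountSet",
    chipInput = "BinnedTrack",
    chipPrecip = "BinnedTrack",
    sequence = "DNAString",
    truth = "LocusConfig"))

setMethod("show", "LocusConfig", function(object) {
    cat(sprintf("LocusConfig: %s:%d-%d (seed %d)\n", object@chrom,
                as.integer(object@locusStart), as.integer(object@locusEnd),
                object@seed))
    cat(sprintf("  %d planted DMR(s), %d SNP(s), %d individual(s), mode %s\n",
                nrow(object@dmrs), nrow(object@snps),
                length(object@individuals), object@expressionMode))
})

setMethod("show", "BinnedTrack", function(object) {
    cat(sprintf("BinnedTrack: %s, %d bins of %d bp from %d\n", object@chrom,
                length(object@values), as.integer(object@binSize),
                as.integer(object@start)))
})

setMethod("show", "LocusSimulation", function(object) {
    cat("LocusSimulation\n")
    cat(sprintf("  methylome : %d CpGs x %d replicates\n",
                nrow(object@methylome), ncol(object@methylome)))
    cat(sprintf("  counts    : %d gDNA, %d RNA, %d precipitate records\n",
                nrow(object@gdnaCounts), nrow(object@rnaCounts),
                nrow(object@precipCounts)))
    cat(sprintf("  tracks    : %d bins; sequence: %d bp\n",
                length(object@chipInput@values), length(object@sequence)))
})
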