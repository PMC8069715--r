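#' @importFrom stats binom.test
NULL

#' Round to integer percents, halves away from zero
#'
#' The rounding convention of the printed allele-percent tables: 37.5 becomes
#' 38 and 62.5 becomes 63 (so a 16-read 6/10 split prints 38\%/63\%).
#'
#' @param x numeric percents.
#' @return integer percents.
#' @export
percentRound <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Reference-allele fraction and printed percents
#'
#' @param refCount,altCount non-negative read counts; reads matching neither
#'   allele are excluded from fractions by convention.
#' @return a data.frame with \code{refFraction}, \code{percentRef},
#'   \code{percentAlt} (integer percents, halves rounded away from zero).
#' @export
allelicFraction <- function(refCount, altCount) {
    total <- refCount + altCount
    if (any(total == 0))
        stop(structure(class = c("imprintKit_zero_depth", "error", "condition"),
                       list(message = "allelic fraction undefined: ref + alt = 0",
                            call = sys.call(-1))))
    f <- refCount / total
    data.frame(refFraction = f,
               percentRef = percentRound(100 * f),
               percentAlt = percentRound(100 * (1 - f)))
}

.acsRows <- function(counts, source) {
    stopifnot(is(counts, "AlleleCountSet"))
    # plain DataFrame so result columns can be appended freely
    as(counts[counts$source == source, , drop = FALSE], "DFrame")
}

#' Classify genotypes from genomic-DNA allele depths
#'
#' A site in one individual is called heterozygous (informative) when total
#' usable depth reaches \code{minDepth} and the minor-allele fraction is at
#' least \code{minMinorFrac}; homozygous when depth suffices and the minor
#' fraction is below 0.05; ambiguous otherwise (including zero depth).
#'
#' @param counts an \linkS4class{AlleleCountSet}; only \code{source == "gDNA"}
#'   rows are classified.
#' @param minDepth minimum ref + alt depth.
#' @param minMinorFrac minimum minor-allele fraction for heterozygosity.
#' @return a \code{DataFrame} of the gDNA rows plus \code{call}
#'   (\code{heterozygous}/\code{homozygous}/\code{ambiguous}),
#'   \code{minorFraction}, \code{percentRef}, \code{percentAlt}.
#' @examples
#' d <- alleleCountSet(data.frame(chrom = "chr1", pos = 21341446,
#'     ref = "C", alt = "T", sampleId = "P1", source = "gDNA",
#'     refCount = 10, altCount = 12))
#' classifyGenotype(d)$call
#' @export
classifyGenotype <- function(counts, minDepth = 10, minMinorFrac = 0.25) {
    x <- .acsRows(counts, "gDNA")
    total <- x$refCount + x$altCount
    minor <- ifelse(total > 0, pmin(x$refCount, x$altCount) / total, NA_real_)
    call <- rep("ambiguous", nrow(x))
    call[total >= minDepth & !is.na(minor) & minor >= minMinorFrac] <- "heterozygous"
    call[total >= minDepth & !is.na(minor) & minor < 0.05] <- "homozygous"
    x$call <- call
    x$minorFraction <- minor
    x$percentRef <- ifelse(total > 0, percentRound(100 * x$refCount / total), NA_integer_)
    x$percentAlt <- ifelse(total > 0, percentRound(100 * x$altCount / total), NA_integer_)
    x
}

#' Screen informative heterozygous SNP / individual pairs
#'
#' Restricts genomic-DNA depths to the given regions, classifies genotypes,
#' and returns the (site, individual) pairs called heterozygous. Sites absent
#' from the variant catalog keep \code{rsId = "NR"} (not reported), mirroring
#' novel informative SNPs discovered from whole-genome sequencing.
#'
#' @param counts an \linkS4class{AlleleCountSet} of gDNA depths.
#' @param catalog optional \code{GRanges} of catalogued SNPs with an
#'   \code{rsId} mcol (as from [readVariantCatalog()]).
#' @param regions optional \code{GRanges}; depths outside are dropped.
#' @param minDepth,minMinorFrac passed to [classifyGenotype()].
#' @return \code{DataFrame} of informative pairs with resolved \code{rsId}.
#' @export
screenInformative <- function(counts, catalog = NULL, regions = NULL,
                              minDepth = 10, minMinorFrac = 0.25) {
    x <- .acsRows(counts, "gDNA")
    if (!is.null(regions) && nrow(x)) {
        gr <- GRanges(x$chrom, IRanges(x$pos, width = 1L))
        x <- x[IRanges::overlapsAny(gr, regions), , drop = FALSE]
    }
    g <- classifyGenotype(alleleCountSet(x), minDepth, minMinorFrac)
    g <- g[g$call == "heterozygous", , drop = FALSE]
    if (nrow(g)) {
        g$rsId <- "NR"
        if (!is.null(catalog) && length(catalog)) {
            key <- paste(as.character(seqnames(catalog)), start(catalog))
            hit <- match(paste(g$chrom, g$pos), key)
            g$rsId[!is.na(hit)] <- catalog$rsId[hit[!is.na(hit)]]
        }
    }
    .log("screenInformative: %d informative (site, individual) pair(s)", nrow(g))
    g
}

#' Classify allelic expression from RNA allele depths
#'
#' Calls per-tissue allelic expression at an informative site:
#' \code{low_coverage} below \code{minDepth}; \code{monoallelic_ref}/
#' \code{monoallelic_alt} when the major-allele percent (printed-percent
#' rounding) reaches \code{100 * monoFrac}; \code{biased} when the major
#' fraction is at least 0.65 with a two-sided binomial p-value against 0.5
#' below 0.05; \code{biallelic} otherwise. The binomial p-value is reported
#' for every call.
#'
#' The monoallelic cut is applied on the rounded-percent scale so that a
#' 2/35 split (94.6\%, printed as 95\%) counts as monoallelic, matching the
#' convention of the published per-tissue tables.
#'
#' @param counts an \linkS4class{AlleleCountSet}; only \code{source == "RNA"}
#'   rows are classified.
#' @param minDepth minimum ref + alt depth for a non-low-coverage call.
#' @param monoFrac monoallelic major-fraction threshold.
#' @return \code{DataFrame} of the RNA rows plus \code{call},
#'   \code{majorFraction}, \code{percentRef}, \code{percentAlt},
#'   \code{pBinomial} and \code{expressedAllele} (\code{"ref"}/\code{"alt"}
#'   for monoallelic calls, \code{NA} otherwise).
#' @export
classifyAllelicExpression <- function(counts, minDepth = 10, monoFrac = 0.95) {
    x <- .acsRows(counts, "RNA")
    n <- nrow(x)
    total <- x$refCount + x$altCount
    fRef <- ifelse(total > 0, x$refCount / total, NA_real_)
    major <- pmax(fRef, 1 - fRef)
    pbin <- rep(NA_real_, n)
    nz <- which(total > 0)
    for (i in nz)
        pbin[i] <- binom.test(x$refCount[i], total[i], p = 0.5,
                              alternative = "two.sided")$p.value
    pctMajor <- ifelse(total > 0, percentRound(100 * major), NA_integer_)
    call <- rep("biallelic", n)
    call[!is.na(pctMajor) & pctMajor >= 100 * monoFrac] <- "monoallelic"
    call[call == "biallelic" & !is.na(major) & major >= 0.65 &
         !is.na(pbin) & pbin < 0.05] <- "biased"
    call[total < minDepth] <- "low_coverage"
    expressed <- rep(NA_character_, n)
    isMono <- call == "monoallelic"
    expressed[isMono] <- ifelse(fRef[isMono] >= 0.5, "ref", "alt")
    call[isMono] <- ifelse(fRef[isMono] >= 0.5,
                           "monoallelic_ref", "monoallelic_alt")
    x$call <- call
    x$majorFraction <- major
    x$percentRef <- ifelse(total > 0, percentRound(100 * fRef), NA_integer_)
    x$percentAlt <- ifelse(total > 0, percentRound(100 * (1 - fRef)), NA_integer_)
    x$pBinomial <- pbin
    x$expressedAllele <- expressed
    x
}

#' Assess cross-tissue maintenance of monoallelic expression
#'
#' For each individual, summarises the expressed allele per informative site
#' and verdicts whether all monoallelic calls at a site name the same allele
#' across tissues (imprinted expression maintained), listing any tissues
#' deviating from the site's majority allele. A cross-site note records
#' whether every usable site in the individual is monoallelic, as expected
#' when all transcript isoforms sharing the locus carry the same imprint.
#'
#' @param calls the \code{DataFrame} returned by
#'   [classifyAllelicExpression()] (needs \code{sampleId}, \code{tissue},
#'   \code{chrom}, \code{pos}, \code{call}, \code{expressedAllele}).
#' @return a named list (class \code{"maintenanceReport"}), one entry per
#'   individual with elements \code{sites} (per-site DataFrame with
#'   \code{expressedAllele}, \code{nCalls}, \code{nMonoallelic},
#'   \code{consistent}, \code{discordantTissues}), \code{allSitesMonoallelic}
#'   and, when an individual has no usable calls, \code{reason}.
#' @export
assessMaintenance <- function(calls) {
    out <- list()
    for (id in unique(calls$sampleId)) {
        cx <- calls[calls$sampleId == id, , drop = FALSE]
        usable <- cx[cx$call != "low_coverage", , drop = FALSE]
        if (!nrow(usable)) {
            out[[id]] <- list(sites = NULL, allSitesMonoallelic = NA,
                              reason = "no usable calls")
            next
        }
        site <- paste0(usable$chrom, ":", usable$pos)
        rows <- lapply(unique(site), function(s) {
            u <- usable[site == s, , drop = FALSE]
            mono <- grepl("^monoallelic", u$call)
            alleles <- u$expressedAllele[mono]
            majority <- if (length(alleles)) names(sort(table(alleles),
                                                        decreasing = TRUE))[1]
                        else NA_character_
            disc <- u$tissue[mono & u$expressedAllele != majority]
            DataFrame(site = s, expressedAllele = majority,
                      nCalls = nrow(u), nMonoallelic = sum(mono),
                      consistent = length(unique(alleles)) <= 1L,
                      discordantTissues = paste(disc, collapse = ","))
        })
        sites <- do.call(rbind, rows)
        out[[id]] <- list(sites = sites,
                          allSitesMonoallelic =
                              all(sites$nMonoallelic == sites$nCalls))
    }
    class(out) <- "maintenanceReport"
    out
}

#' @export
print.maintenanceReport <- function(x, ...) {
    for (id in names(x)) {
        cat(id, ":\n", sep = "")
        if (is.null(x[[id]]$sites)) {
            cat("  ", x[[id]]$reason, "\n", sep = "")
            next
        }
        s <- x[[id]]$sites
        for (i in seq_len(nrow(s)))
            cat(sprintf("  %s expressed=%s calls=%d mono=%d %s%s\n",
                        s$site[i], s$expressedAllele[i], s$nCalls[i],
                        s$nMonoallelic[i],
                        if (s$consistent[i]) "consistent" else "INCONSISTENT",
                        if (nzchar(s$discordantTissues[i]))
                            paste0(" (", s$discordantTissues[i], ")") else ""))
        cat(sprintf("  all sites monoallelic: %s\n",
                    x[[id]]$allSitesMonoallelic))
    }
    invisible(x)
}
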