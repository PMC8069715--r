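#' @importFrom utils read.delim write.table
NULL

.methCols <- c("chrom", "pos", "strand", "context", "ratio",
               "methylated", "total")

#' Read a per-CpG methylation-ratio table
#'
#' Reads a BSMAP-methratio-style TSV with header columns \code{chrom},
#' \code{pos} (1-based cytosine coordinate), \code{strand}, \code{context},
#' \code{ratio}, \code{methylated}, \code{total}. Rows are validated
#' (ratio within [0, 1] and consistent with the counts to within
#' \code{0.5/total}, for pre-rounded inputs); offending rows are reported
#' with their line number. Unsorted input is sorted with a warning.
#'
#' With \code{strandMerge = TRUE}, plus- and minus-strand records of one CpG
#' dinucleotide are pooled by summed counts into a single site at the
#' plus-strand C position (the minus-strand G sits one base downstream).
#' The default keeps strands separate, since per-strand cytosines are
#' counted individually in the published DMR figures.
#'
#' @param path TSV path.
#' @param strandMerge pool the two strands of each CpG dinucleotide?
#' @return data.frame with the columns above, sorted by position.
#' @export
readMethylationTable <- function(path, strandMerge = FALSE) {
    x <- read.delim(path, stringsAsFactors = FALSE)
    missing <- setdiff(.methCols, names(x))
    if (length(missing))
        stop("missing methylation-table columns: ",
             paste(missing, collapse = ", "))
    line <- seq_len(nrow(x)) + 1L  # header is line 1
    bad <- which(is.na(x$ratio) | x$ratio < 0 | x$ratio > 1)
    if (length(bad))
        stop(sprintf("line %d: methylation ratio %s outside [0, 1]",
                     line[bad[1]], format(x$ratio[bad[1]])))
    bad <- which(x$methylated < 0 | x$methylated > x$total)
    if (length(bad))
        stop(sprintf("line %d: methylated count inconsistent with total",
                     line[bad[1]]))
    withTot <- which(x$total > 0)
    bad <- withTot[abs(x$ratio[withTot] -
                       x$methylated[withTot] / x$total[withTot]) >
                   0.5 / x$total[withTot] + 1e-9]
    if (length(bad))
        stop(sprintf("line %d: ratio does not match methylated/total",
                     line[bad[1]]))
    o <- order(x$chrom, x$pos)
    if (!identical(o, seq_len(nrow(x)))) {
        warning("methylation table was not sorted; sorting by position")
        x <- x[o, , drop = FALSE]
    }
    if (strandMerge) {
        plusAt <- ifelse(x$strand == "-", x$pos - 1L, x$pos)
        key <- paste(x$chrom, plusAt)
        meth <- tapply(x$methylated, key, sum)
        tot <- tapply(x$total, key, sum)
        first <- !duplicated(key)
        y <- data.frame(chrom = x$chrom[first], pos = plusAt[first],
                        strand = "+", context = x$context[first],
                        stringsAsFactors = FALSE)
        k <- paste(y$chrom, y$pos)
        y$methylated <- as.integer(meth[k])
        y$total <- as.integer(tot[k])
        y$ratio <- ifelse(y$total > 0, y$methylated / y$total, NA_real_)
        x <- y[order(y$chrom, y$pos), .methCols]
    }
    rownames(x) <- NULL
    .log("readMethylationTable: %d site(s) from %s", nrow(x), path)
    x
}

#' Write a per-CpG methylation-ratio table
#'
#' @param x data.frame in the layout of [readMethylationTable()].
#' @param path output TSV path.
#' @export
writeMethylationTable <- function(x, path) {
    stopifnot(all(.methCols %in% names(x)))
    write.table(x[, .methCols], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read an allele-count table
#'
#' TSV dialect with header columns \code{chrom}, \code{pos}, \code{ref},
#' \code{alt}, \code{rs_id}, \code{sample}, \code{source}, \code{tissue},
#' \code{ref_count}, \code{alt_count}, \code{other_count}. Empty strings and
#' \code{"."} in \code{rs_id}/\code{tissue} become \code{NA}.
#'
#' @param path TSV path.
#' @return an \linkS4class{AlleleCountSet}.
#' @export
readAlleleCounts <- function(path) {
    x <- read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", "", "."),
                    colClasses = c(ref = "character", alt = "character",
                                   sample = "character"))
    fileCols <- c(chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
                  rsId = "rs_id", sampleId = "sample", source = "source",
                  tissue = "tissue", refCount = "ref_count",
                  altCount = "alt_count", otherCount = "other_count")
    missing <- setdiff(unname(fileCols), names(x))
    if (length(missing))
        stop("missing allele-count columns: ", paste(missing, collapse = ", "))
    y <- x[, unname(fileCols)]
    names(y) <- names(fileCols)
    y$tissue <- as.character(y$tissue)
    y$rsId <- as.character(y$rsId)
    alleleCountSet(y)
}

#' Write an allele-count table
#'
#' @param counts an \linkS4class{AlleleCountSet} (or coercible data.frame).
#' @param path output TSV path.
#' @export
writeAlleleCounts <- function(counts, path) {
    x <- as.data.frame(counts)
    out <- data.frame(chrom = x$chrom, pos = x$pos, ref = x$ref,
                      alt = x$alt, rs_id = x$rsId, sample = x$sampleId,
                      source = x$source, tissue = x$tissue,
                      ref_count = x$refCount, alt_count = x$altCount,
                      other_count = x$otherCount)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a variant catalog from VCF
#'
#' Consumes only CHROM, POS, ID, REF and ALT. Multiallelic records are split
#' into one biallelic record per alternate allele; records that are not
#' simple SNPs (indels, structural alleles) are skipped with a logged count.
#'
#' @param path VCF (v4.x) path.
#' @return a \code{GRanges} of SNPs with mcols \code{ref}, \code{alt},
#'   \code{rsId} (\code{NA} where the VCF carries no rs identifier).
#' @export
readVariantCatalog <- function(path) {
    v <- VariantAnnotation::readVcf(path)
    if (!nrow(v))
        return(GRanges(seqnames = character(), ranges = IRanges(),
                       ref = character(), alt = character(),
                       rsId = character()))
    ids <- rep(names(SummarizedExperiment::rowRanges(v)),
               S4Vectors::elementNROWS(VariantAnnotation::alt(v)))
    ve <- VariantAnnotation::expand(v)
    rr <- SummarizedExperiment::rowRanges(ve)
    refA <- as.character(VariantAnnotation::ref(ve))
    altA <- as.character(VariantAnnotation::alt(ve))
    isSnp <- nchar(refA) == 1L & nchar(altA) == 1L &
        refA %in% c("A", "C", "G", "T") & altA %in% c("A", "C", "G", "T")
    if (any(!isSnp))
        .log("readVariantCatalog: skipped %d non-SNP record(s)", sum(!isSnp))
    rsId <- ifelse(grepl("^rs", ids), ids, NA_character_)
    out <- GRanges(seqnames(rr)[isSnp],
                   IRanges(start(rr)[isSnp], width = 1L),
                   ref = refA[isSnp], alt = altA[isSnp], rsId = rsId[isSnp])
    .log("readVariantCatalog: %d SNP record(s) from %s", length(out), path)
    out
}

#' Write a minimal VCF of SNP sites
#'
#' @param snps data.frame with \code{pos}, \code{ref}, \code{alt},
#'   \code{rsId} columns.
#' @param chrom chromosome name.
#' @param path output path.
#' @export
writeSnpVcf <- function(snps, chrom, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s>", chrom),
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", sep = "\t")), con)
    for (i in seq_len(nrow(snps)))
        writeLines(paste(chrom, as.integer(snps$pos[i]),
                         ifelse(is.na(snps$rsId[i]), ".", snps$rsId[i]),
                         snps$ref[i], snps$alt[i], ".", ".", ".",
                         sep = "\t"), con)
    invisible(path)
}

#' Write intervals as BED
#'
#' Converts 1-based inclusive intervals to BED's 0-based half-open
#' convention (\code{[s, e]} becomes \code{[s-1, e)}) and writes a BED6 line
#' per record, sorted by chromosome and start, followed by any extra mcols
#' as additional columns. Works for DMR, peak and CpG-island \code{GRanges}.
#'
#' @param gr a \code{GRanges} with 1-based inclusive ranges.
#' @param path output path.
#' @param scoreCol optional mcol used for the BED score field; DMR tables
#'   conventionally use \code{-log10(qValue)}.
#' @param trackName value for the \code{track name=} header line.
#' @export
writeBed <- function(gr, path, scoreCol = NULL, trackName = "imprintKit") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track name=%s", trackName), con)
    if (!length(gr)) return(invisible(path))
    gr <- GenomicRanges::sort(gr)
    score <- if (!is.null(scoreCol) && scoreCol %in%
                 names(S4Vectors::mcols(gr)))
        S4Vectors::mcols(gr)[[scoreCol]] else rep(0, length(gr))
    extra <- S4Vectors::mcols(gr)
    name <- if ("name" %in% names(extra)) extra$name
            else paste0("region_", seq_along(gr))
    fields <- cbind(as.character(seqnames(gr)),
                    format(start(gr) - 1L, scientific = FALSE, trim = TRUE),
                    format(end(gr), scientific = FALSE, trim = TRUE),
                    name, format(score, trim = TRUE), ".")
    if (ncol(extra))
        fields <- cbind(fields, as.matrix(format(as.data.frame(extra),
                                                 trim = TRUE)))
    writeLines(apply(fields, 1L, paste, collapse = "\t"), con)
    invisible(path)
}

#' Read and write bedGraph coverage tracks
#'
#' bedGraph is 0-based half-open on disk; in memory the package uses
#' 1-based inclusive \linkS4class{BinnedTrack} bins. Conversion is confined
#' to this border and is an exact bijection.
#'
#' @param track a \linkS4class{BinnedTrack}.
#' @param path file path.
#' @return \code{readBedGraphTrack} returns a \linkS4class{BinnedTrack}.
#' @name bedgraph-io
NULL

#' @rdname bedgraph-io
#' @export
writeBedGraphTrack <- function(track, path) {
    gr <- trackAsGRanges(track)
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' @rdname bedgraph-io
#' @export
readBedGraphTrack <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    grangesAsTrack(gr)
}

#' Write a simulated locus bundle to disk
#'
#' Emits every file dialect the pipeline consumes: one methylation TSV per
#' replicate, allele-count TSVs for gDNA, RNA and ChIP precipitate, input
#' and precipitate bedGraph tracks, the locus FASTA, a minimal VCF of the
#' configured SNPs, and a ground-truth JSON sidecar.
#'
#' @param sim a \linkS4class{LocusSimulation}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    stopifnot(is(sim, "LocusSimulation"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    me <- sim@methylome
    rr <- SummarizedExperiment::rowRanges(me)
    for (j in seq_len(ncol(me))) {
        df <- data.frame(
            chrom = as.character(seqnames(rr)),
            pos = start(rr), strand = "+", context = "CG",
            ratio = SummarizedExperiment::assay(me, "ratio")[, j],
            methylated = SummarizedExperiment::assay(me, "methylated")[, j],
            total = SummarizedExperiment::assay(me, "total")[, j])
        writeMethylationTable(df, file.path(dir,
            sprintf("methylation_%s.tsv", colnames(me)[j])))
    }
    writeAlleleCounts(sim@gdnaCounts, file.path(dir, "gdna_counts.tsv"))
    writeAlleleCounts(sim@rnaCounts, file.path(dir, "rna_counts.tsv"))
    writeAlleleCounts(sim@precipCounts, file.path(dir, "precip_counts.tsv"))
    writeBedGraphTrack(sim@chipInput, file.path(dir, "chip_input.bedGraph"))
    writeBedGraphTrack(sim@chipPrecip, file.path(dir, "chip_precip.bedGraph"))
    ss <- DNAStringSet(sim@sequence)
    names(ss) <- sprintf("%s:%d-%d", sim@truth@chrom,
                         as.integer(sim@truth@locusStart),
                         as.integer(sim@truth@locusEnd))
    writeXStringSet(ss, file.path(dir, "sequence.fa"))
    if (nrow(sim@truth@snps))
        writeSnpVcf(sim@truth@snps, sim@truth@chrom,
                    file.path(dir, "snps.vcf"))
    jsonlite::write_json(configAsList(sim@truth),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

#' Serialise a LocusConfig to a plain list
#'
#' @param config a \linkS4class{LocusConfig}.
#' @return a named list mirroring the slots (ground-truth JSON layout).
#' @export
configAsList <- function(config) {
    sl <- slotNames(config)
    out <- lapply(sl, function(s) {
        v <- slot(config, s)
        if (is.matrix(v)) apply(v, 2, identity, simplify = FALSE)
        else if (is.data.frame(v)) as.list(v)
        else v
    })
    names(out) <- sl
    out
}
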