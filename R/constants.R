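#' Reported annotation of the porcine PLAGL1 locus (Sscrofa11.1)
#'
#' 1-based inclusive coordinates of the landmark intervals on chromosome 1
#' used throughout the package's worked examples and as the template for the
#' synthetic locus defaults: the first (promoter/CpG-island) DMR, the CpG
#' island inside it, and the second (intron 3-4) DMR that holds exactly ten
#' differentially methylated CpGs. Coordinates are treated as opaque labels;
#' the reference genome itself is never fetched.
#'
#' @return a data.frame with columns \code{name}, \code{chrom}, \code{start},
#'   \code{end}.
#' @examples
#' ann <- plagl1Annotation()
#' intervalLength(ann$start, ann$end)
#' @export
plagl1Annotation <- function() {
    data.frame(
        name = c("dmr1", "cpg_island", "dmr2"),
        chrom = "chr1",
        start = c(21303256, 21303765, 21337135),
        end = c(21305675, 21304604, 21337358))
}

#' Reported CTCF precipitate allele counts at the porcine PLAGL1 boundary
#'
#' T/C read counts recovered by CTCF ChIP at the heterozygous site
#' immediately downstream of the last exon in two pig embryonic fibroblast
#' lines, with the input allele fractions (T 25\%, C 75\%). Both precipitates
#' are the canonical biallelic-binding example for
#' [classifyPrecipitation()].
#'
#' @return a data.frame with one row per fibroblast line and columns
#'   \code{sample}, \code{tCount}, \code{cCount}, \code{inputTFrac}.
#' @export
pefPrecipitationCounts <- function() {
    data.frame(sample = c("PEF1", "PEF2"),
               tCount = c(88L, 222L),
               cCount = c(65L, 193L),
               inputTFrac = 0.25)
}

#' Adult pig tissue vocabulary
#'
#' The seven-tissue panel used for per-tissue allelic-expression tables:
#' adipose, brain, liver, lung, skeletal muscle, heart, ovary.
#'
#' @return named character vector of tissue codes.
#' @export
pigTissues <- function() {
    c(adipose = "Ad", brain = "Br", liver = "Lv", lung = "Ln",
      muscle = "Mu", heart = "Hr", ovary = "Ov")
}

#' Path to the bundled allele-count table of the adult-pig SNP screen
#'
#' The published per-site read counts of each allele (genomic DNA from
#' skeletal muscle plus RNA from adipose, lung, heart and ovary, pigs P1-P3)
#' at the four exonic SNP sites of the porcine PLAGL1 locus, in the package's
#' allele-count TSV dialect.
#'
#' @return file path of the TSV.
#' @export
plagl1CountsFile <- function() {
    system.file("extdata", "plagl1_table1_counts.tsv",
                package = "imprintKit", mustWork = TRUE)
}

#' Path to the bundled SNP catalog fixture
#'
#' A minimal VCF holding the three catalogued SNPs of the adult-pig screen
#' (plus non-SNP records exercising the reader's skip paths).
#'
#' @return file path of the VCF.
#' @export
plagl1CatalogFile <- function() {
    system.file("extdata", "plagl1_snps.vcf",
                package = "imprintKit", mustWork = TRUE)
}
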