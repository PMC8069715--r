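---
title: "Characterising an imprinted locus: methods and design notes"
author: "imprintKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising an imprinted locus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintKit)
options(imprintKit.logLevel = "quiet")
```

# The scientific setting

Genomic imprinting marks one parental allele of a gene with DNA methylation
laid down in the germ line, silencing it in *cis* and leaving the other
allele as the sole template for transcription. A maternally methylated
control region therefore shows up in two complementary data types:

* **Methylomes.** Comparing embryos carrying two maternal genomes
  (parthenogenetic, "PA") against biparental controls ("CN") doubles the
  dose of maternal methylation marks: a maternally methylated region is
  *hypermethylated* in the PA group. Whole-genome bisulfite sequencing
  summarised as per-CpG methylation ratios is the input.
* **Allele-resolved transcriptomes.** At a SNP that is heterozygous in an
  individual's genomic DNA (an *informative* site), RNA reads can be
  assigned to alleles. Under imprinting, essentially all RNA reads carry
  one allele — here the paternal one — in every expressing tissue, and the
  expressed allele stays the same across tissues and developmental stages.

Two further genomic features frame such a locus: a CpG island typically
overlaps the imprinted promoter, and the imprinted transcription unit lies
between CTCF-enriched topological boundary regions, where CTCF binds both
alleles (biallelic ChIP precipitation) when the boundary itself is
unmethylated on both chromosomes.

imprintKit implements each of these analyses at desk scale, plus a seeded
synthetic-locus generator whose ground truth makes the whole pipeline
testable end to end. The worked examples and bundled fixtures follow the
porcine *PLAGL1* locus on chromosome 1 (Sscrofa11.1 coordinates), whose
published per-site allele counts ship with the package.

# Differentially methylated region calling

`callDmrs()` composes four stages, each exposed on its own:

1. **Per-site contrast** (`siteDelta()`): for every CpG, the difference of
   group-mean methylation ratios, group A (maternal-duplicate) minus group
   B. A site needs at least two usable replicate values per group;
   otherwise it is set aside (it neither seeds nor breaks a region).
2. **Flagging** (`flagDmCpgs()`): a CpG is differentially methylated when
   `|delta| > minDelta` (default 0.2, strict), keeping the sign.
3. **Segmentation** (`segmentCandidates()`): candidate regions are maximal
   runs of same-sign flagged CpGs in which consecutive *flagged* CpGs are
   less than `maxGap` bp apart (default 300, strict), holding at least
   `minCpgs` flagged CpGs (default 10). The gap rule deliberately binds the
   differentially methylated CpGs themselves: an interleaved unflagged CpG
   does not split a region, because the criterion describes the spacing of
   the differential signal, not of the CpG landscape.
4. **Region test** (`testRegions()`): a two-sided Mann–Whitney U test
   compares the per-CpG group means of the two groups across the region's
   flagged CpGs — exact null when both sides have at most 12 values and no
   ties, normal approximation with tie correction otherwise — followed by
   Benjamini–Hochberg adjustment across all candidates of the run (the
   multiple-testing family is one invocation of the caller). Emitted
   regions additionally satisfy `|deltaAve| > minDelta` at the region
   level and `qValue < fdr` (default 0.05, strict). Direction is
   `maternal_hyper` when group A is the more methylated.

Region bounds are the first and last flagged CpG, 1-based inclusive;
`writeBed()` converts to BED's 0-based half-open convention only at the
file border. Two degenerate cases are defined, not errors: identical
constant values in both groups give p = 1, and an empty input gives an
empty `GRanges`.

The region statistic is a deliberate design choice. Production callers for
this design use binary segmentation with a two-dimensional
Kolmogorov–Smirnov statistic; re-implementing that machinery is out of
scope here, and the Mann–Whitney composition over the explicit threshold
criteria is reproducible, exactly testable (the suite checks the exact
branch against exhaustive rank enumeration), and consistent with the
secondary statistic such callers report.

```{r dmr-example}
sim <- simulateLocus(locusConfig(seed = 7))
callDmrs(methylome(sim))
```

# Informative SNPs and allelic expression

`classifyGenotype()` calls a site heterozygous in one individual when the
ref+alt depth reaches 10 and the minor-allele fraction is at least 0.25,
homozygous when the minor fraction is below 0.05 at sufficient depth, and
ambiguous otherwise. The thresholds were chosen so that every published
informative genomic-DNA row (minor fractions 0.32–0.47, depths 15–37)
qualifies while fractions at sequencing-error level never do.
`screenInformative()` applies this over a region set and resolves catalog
identifiers; sites absent from the catalog are kept and labelled `NR`
(not reported), since a novel heterozygous exonic SNP is just as
informative as a catalogued one.

`classifyAllelicExpression()` reports, per RNA record, integer percents
under the table convention (halves round away from zero: a 6/10 split
prints 38%/63%), a two-sided binomial p-value against 0.5, and a call:
`low_coverage` under 10 usable reads, `monoallelic_ref`/`monoallelic_alt`
when the major-allele percent reaches 95, `biased` when the major fraction
is at least 0.65 with binomial p < 0.05, `biallelic` otherwise. The
monoallelic cut is applied on the *rounded-percent* scale: the published
lung call with a 2/35 split has a raw major fraction of 0.946 yet is
printed, and interpreted, as 95% monoallelic expression; applying the
threshold to the raw fraction would contradict that worked example.
Reads matching neither configured allele are excluded from fractions but
carried through (`otherCount`), matching how the published fractions are
computed over ref+alt only.

Parental origin is deliberately *not* inferred at this stage: adult
samples carry no trio information, so calls name ref/alt alleles and
parental attribution stays with the caller (in the embryo design, the
methylome contrast carries the parent-of-origin evidence).

`assessMaintenance()` summarises, per individual and site, whether all
monoallelic calls name the same allele across tissues, listing tissues
that deviate from the site's majority allele, plus a note on whether every
usable site is monoallelic — the expectation when all transcript isoforms
share the locus imprint. One known bookkeeping subtlety in the source
material: the running text and the printed table disagree about which pig
carries the novel exon-7 SNP versus the catalogued last-exon SNP; the
bundled fixture follows the table, and the package does not attempt to
adjudicate.

```{r ase-example}
counts <- readAlleleCounts(plagl1CountsFile())
inf <- screenInformative(counts, catalog = readVariantCatalog(plagl1CatalogFile()))
as.data.frame(inf[, c("pos", "rsId", "sampleId", "percentRef", "percentAlt")])
```

# CTCF boundary regions

`detectEnrichedRegions()` is a deterministic run detector: background is
the median bin value with a floor of one coverage unit, and peaks are
maximal runs of bins at least `minFold` (default 5) times background, at
least `minWidth` (default 200 bp) wide, with runs separated by a single
below-threshold bin merged. The floor exists only so an empty or
near-empty track cannot produce a zero background; because the threshold
is otherwise relative, rescaling a track leaves the peak set unchanged.
No peak-caller is prescribed for this analysis in the source design —
enrichment is shown visually — so the simplest auditable detector with an
exposed fold threshold was preferred.

`flankingBoundaryGap()` picks the nearest qualifying peak on each side of
the transcription unit (downstream peaks may overlap the unit's last exon)
and measures the gap **apex to apex** — published boundary gaps are
approximate, and apex-to-apex is the only unambiguous single number.
Missing flanks raise errors naming the side.

`classifyPrecipitation()` tests ChIP precipitate allele counts:
`biallelic` when both allele fractions reach 0.25 at depth 20 or more
(both published fibroblast precipitates, with 42% and 47% minor alleles,
qualify comfortably, while allele-specific binding seen at other imprinted
loci does not), `allele_specific` below a 0.05 minor fraction, and
`inconclusive` otherwise — including sites with no heterozygous input
allele, which are *untestable* rather than biallelic. With input
fractions supplied, a binomial p-value of the precipitate against the
input reference fraction is reported as an enrichment-shift note.

# Sequence annotation

`windowStats()` reports GC fraction and the CpG observed/expected ratio
`count(CG) / (count(C) x count(G) / length)` in sliding windows; Ns are
excluded from numerator and denominator, windows over 50% N are skipped,
and a final partial window is kept when at least half a window remains.
`findCpgIslands()` applies the classical criteria — 200-bp windows stepped
by 1 bp with GC > 0.5 and observed/expected > 0.6, merged when
overlapping, re-checked as merged intervals, minimum length 200 bp. The
source analysis names its CpG island without stating a definition, so the
de-facto genome-browser standard is used with every threshold exposed.
Because CG is its own reverse complement as a dinucleotide pattern, island
calls are reverse-complement invariant, which the suite checks.

# The synthetic locus

`locusConfig()`/`simulateLocus()` generate a full locus bundle with known
truth. Defaults describe a 90-kb virtual locus modelled on the porcine
*PLAGL1* region; every parameter is a named argument.

* **CpG placement.** CpGs sit on a jittered lattice (spacing
  1000/density, uniform jitter of a quarter spacing): real CpG spacing is
  clustered, and a homogeneous Poisson draw would plant >300-bp gaps
  inside a DMR with appreciable probability, making ground truth itself
  ill-defined. Background density defaults to 10 CpGs/kb; planted DMRs
  carry their own densities (the small intronic DMR packs 10 CpGs into
  224 bp, mirroring the published geometry).
* **Methylation noise.** Per-CpG, per-replicate ratios are beta draws
  around the site mean with concentration 20 — bounded in [0, 1] with
  realistic replicate scatter. Counts-level simulation is intentionally
  omitted; the written tables carry derived, rounded methylated/total
  counts consistent with the ratio to within the reader's documented
  0.5/total tolerance. Planted DMRs default to group means 0.90
  (maternal-duplicate) versus 0.45, i.e. a delta of 0.45 over a
  background of 0.70 in both groups.
* **Haplotypes and expression.** Each individual carries two phased
  haplotypes written `"M|P"`; no recombination is modelled at single-locus
  scale. Under `monoallelic_paternal`, RNA allele counts at heterozygous
  sites are beta-binomial with the paternal allele as the major one, so
  phase consistency holds by construction. `purity` (default 0.98) is the
  guaranteed *floor* on the expected paternal fraction; the simulated mean
  fraction is `(1 + purity)/2` = 0.99, matching the ~1% minor-read
  leakage observable in the published per-tissue counts (97–100%
  monoallelic fractions). RNA depth defaults to a Poisson mean of 60 reads
  per site and tissue — the upper range of the published exonic depths
  (11–65) — with beta-binomial concentration 100; genomic DNA depth
  defaults to 25. Per-tissue overrides (`tissueModes`) simulate
  reversed-imprint tissues for negative controls.
* **ChIP tracks.** Input is Poisson background (mean 20 per 200-bp bin);
  the precipitate adds Gaussian-shaped enrichment (default 10-fold,
  800 bp wide) at the configured peak centers. Precipitate allele counts
  at SNP sites are beta-binomial around 0.5, emulating biallelic CTCF
  binding.
* **Sequence.** A CpG-depleted AT-leaning background (80% of CG
  dinucleotides disrupted, observed/expected ~0.2) with one planted
  GC-rich segment (GC ~0.66, observed/expected ~1) at the configured
  island interval.

What the generator does *not* emulate: read-level artefacts (bisulfite
conversion failure, mapping bias toward the reference allele, PCR
duplicates), copy-number variation, cell-type mixtures, or genome-scale
heterogeneity of methylation. Passing tests therefore demonstrate the
statistical machinery under the stated noise model, not robustness to
upstream processing artefacts — inputs are taken at the
processed-summary contract (methylation ratios, allele depths, normalized
coverage).

`simulateNullMethylomes()` applies no DMR intervals, giving the type-I
calibration target: with the default criteria, 50 null replicates of
2,000 CpGs at n = 3 vs 3 yield a mean called-DMR count of about zero
(bounded at 0.25 in the acceptance suite).

# Calibration problem sizes and numerical notes

The shipped calibration suites use: 50 null methylomes of 2,000 CpGs
(n = 3 vs 3) for false positives; 40 planted-locus replicates with a
1.5-kb, 30-CpG DMR (delta 0.45) for recovery with boundary error at most
two CpG spacings — planted comfortably above the 10-CpG calling minimum so
the rate measures boundary accuracy rather than knife-edge flag
fluctuation, the minimum-count behaviour having its own exact checks —
and 10 monoallelic simulations (~280 tissue calls at depth >= 20) for
allelic-expression recovery at or above 95%. These sizes were chosen so
each suite has clear statistical margin while remaining a desk-scale
computation.

Numerical conventions worth knowing:

* Strict inequalities everywhere the criteria say "more than" / "less
  than": a delta of exactly 0.2 is not flagged, a 300-bp gap splits.
* The exact Mann–Whitney branch requires no ties; with ties the normal
  approximation with tie correction is used. All-constant input returns
  p = 1.
* `percentRound()` rounds halves away from zero — the only convention
  that reproduces every printed percent pair (including 37.5/62.5 to
  38/63).
* Internally all coordinates are 1-based inclusive; BED/bedGraph
  conversion is confined to the readers/writers and is an exact
  bijection.
* Strand merging of CpG records (minus-strand G pooled onto the
  plus-strand C one base upstream) is available in
  `readMethylationTable()` but off by default, since the published
  per-site figures count the two strands' cytosines separately.

# Limitations

The DMR caller is a desk-scale reference implementation of explicit
criteria, not a genome-wide segmentation engine; its boundary placement
inherits the threshold character of the criteria (a chance-flagged
background CpG within `maxGap` of a region edge extends the region). The
boundary-gap number depends on the peak definition and should be read at
the precision of the published approximate gaps (tens of kb). The
maintenance report treats tissues as exchangeable labels and does not
model tissue-specific imprinting strength, only call-level consistency.
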