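---
title: "Scanning RAD-seq haplotype data for signatures of balancing selection"
author: "balscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning RAD-seq haplotype data for signatures of balancing selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balscan)
```

## The problem

Balancing selection (frequency dependence, heterozygote advantage,
spatially or temporally fluctuating selection) maintains polymorphism for
long periods, which leaves three classic footprints in population data:
locally **elevated polymorphism**, a shift of the site-frequency spectrum
towards **intermediate allele frequencies** (positive Tajima's D), and
**reduced differentiation** (F\_ST) among populations relative to the
genomic background. Geographically diversifying selection leaves the
complementary footprint of elevated polymorphism *with* elevated
differentiation. Single outlier loci are fragile evidence — a single
mis-assembled tag can mimic a balanced polymorphism — so the scan
implemented here aggregates sparse RAD markers into kernel-smoothed
windows and asks where several signatures coincide, and whether a
candidate gene class expected to be under pathogen-mediated selection
(NLR-type disease-resistance genes) is over-represented there, against a
control class (LRR-RLK receptor kinases) where no such enrichment is
expected.

`balscan` implements the full chain for diploid RAD-seq data genotyped as
whole-tag haplotypes (the classic 92-bp tag): per-locus diversity
statistics, smoothed-window outlier detection with a bootstrap null,
window merging, sliding-window Tajima's D from SNP genotypes, AMOVA-based
F\_ST, interval overlap between signature sets, and a label-permutation
enrichment test for gene classes — plus a synthetic-data generator with
planted truth so the whole chain can be validated end to end.

## Statistics at a single RAD locus

A RAD locus is genotyped in each diploid individual as an unordered pair
of haplotype alleles (full 92-bp sequences, so linked SNPs inside the tag
stay linked). With `n` genotyped individuals (2n sequences) at one locus:

* **Nucleotide diversity** `locusPi()`: the mean number of nucleotide
  differences over all C(2n, 2) unordered pairs of sequences, divided by
  the tag length — the classic pairwise estimator with haplotypes as
  alleles. No additional small-sample factor is applied on top of the
  pairwise definition; the divisor is the locus length stored in the
  locus table.
* **Gene diversity** `locusGeneDiversity()`: with haplotype frequencies
  `p_k` over the 2n sequences, `He = (2n/(2n-1)) (1 - sum p_k^2)`. The
  leading unbiased correction follows Nei's small-sample form; it is
  configurable (`unbiased = FALSE`) because haplotype-pipeline
  implementations differ on this point and the choice matters at the
  small group sizes typical of broad geographic sampling.
* **Observed heterozygosity** `locusObservedHet()`: the proportion of
  genotyped individuals whose two haplotypes differ. Pairs are stored in
  canonical (lexicographic) order so heterozygote counting is independent
  of representation. The per-individual analogue
  (`individualHeterozygosity()`) divides heterozygous loci by genotyped
  loci per individual, over a locus set that includes monomorphic loci.
* **AMOVA F\_ST** `locusAmovaFst()`: haplotypes are treated as unordered
  alleles and the allelic variance of the 2n sequences is partitioned
  among versus within populations (one-level AMOVA with binary allele
  mismatch). Negative estimates are reported as computed — clipping is a
  presentation decision, and unclipped values are needed for unbiased
  averaging. The distance-based Phi\_ST variant (weighting allele pairs
  by sequence divergence) is deliberately not used: the scan treats
  haplotypes as exchangeable alleles.
* **Pairwise population F\_ST** `pairwiseFst()`: the Weir–Cockerham
  (1984) estimator, multiallelic, as a ratio of variance-component sums
  over loci and alleles, plus the linearized distance `F_ST/(1 - F_ST)`
  used by the isolation-by-distance regression (`ibdRegression()`, with
  great-circle distances at an Earth radius of 6371 km and significance
  from permuting rows and columns of the genetic matrix together).

Loci are first filtered by presence (`filterLociByPresence()`): a locus
is kept for a sample group when it is genotyped in at least
`ceil((1 - max_missing_frac) * n)` group members. The two strategies the
package reports side by side are 0% missing (present in all) and up to
50% missing; relaxed filtering keeps the highly polymorphic loci that
drop out of strict filtering precisely because divergent alleles fail to
align, which is where balanced polymorphisms are expected to hide.

## The smoothed-window scan

Windows are centred on every polymorphic RAD locus. With smoothing scale
`sigma` (bp), a window spans 3`sigma` either side of its centre and the
smoothed value is the weighted mean of the per-locus statistic with
Gaussian kernel weights `exp(-d^2 / (2 sigma^2))` — the centre locus
carries weight 1, a locus at distance `sigma` carries 0.607, and the
kernel is truncated at 3`sigma`. `sigma` is always explicit in the scan
configuration; `sigmaForLocusDensity()` returns the value for which a
window holds ~30 loci on average (60 kbp at the typical 12 kbp marker
spacing), the convention used throughout. Weighting each locus further by
its allele-count information is a known option in this family of scans;
it is omitted here (hook available) because equal per-locus weighting is
the simpler defensible default when tag depths are already filtered.

Significance of elevated diversity is assessed by bootstrap
(`bootstrapWindowPvalues()`): each pseudoreplicate redraws the window's
`m` contributing loci with replacement from the genome-wide per-locus
pool and recomputes the weighted mean with the window's own kernel
weights; the upper-tail p-value uses the add-one correction
`(1 + #[rep >= obs]) / (n_reps + 1)`, so p can never be an artefactual
zero. The default is 10,000 pseudoreplicates; production runs of this
scan family use up to 10^6, and the tests here scale down to 500–2,000,
which bounds the attainable p at ~5e-4–2e-3 — ample for a 0.05 threshold.
A window is "high diversity" when significant for He **or** pi at the
alpha threshold, with the three mutually exclusive reporting categories
(He only, pi only, both) kept additive in the summary table.

Runs of significant windows merge into regions
(`mergeWindowsToRegions()`) when consecutive centres are separated by
less than `sigma`; a region spans from the first centre minus `sigma` to
the last centre plus `sigma`, clipped to chromosome bounds. The source
description of this merging rule is ambiguous between centre distance
and window-edge overlap (6`sigma` windows overlap long before centres are
within `sigma`); the centre-distance reading is adopted because it
reproduces compact regions rather than chaining half the chromosome, and
merging is idempotent under it.

F\_ST windows reuse the same smoothing; extremes are selected by
empirical nearest-rank quantile (`quantileWindows()`, bottom/top 5%),
not by bootstrap — differentiation extremes are defined relative to the
distribution of windows, not a resampling null. Single-locus outliers
(`singleLocusOutliers()`, top 1% with ties included) are retained for
comparison with the smoothed approach; no manual assembly-based
exclusions are applied.

## Sliding-window Tajima's D

Tajima's D uses individual SNPs, not haplotypes, on a fixed grid
(`slidingTajimaD()`): 120 kbp windows advancing by 12 kbp (the average
marker spacing), anchored at coordinate 1 of each chromosome — the
anchor is a free choice and is fixed so runs are reproducible. Per
window, `S` counts polymorphic sites and `pihat` sums per-site pairwise
difference proportions over the non-missing sequences;
`D = (pihat - S/a1) / sqrt(e1 S + e2 S (S-1))` with the Tajima (1989)
constants. With missing genotypes the per-site sample size varies inside
a window; the constants use the median per-site non-missing sequence
count (rounded), a pragmatic rule the classic formula does not address.
Windows with `S = 0` are counted but flagged not estimable, and the top
5% of estimable windows are selected at exactly `round(0.05 * n)`
(`topDWindows()`), ties at the boundary resolved by genomic order —
`round()` is adopted because it reproduces the published overlap
percentages of this scan family under nearest-integer arithmetic.

## Gene-class enrichment

Genes come from GFF3 (`readGff3Genes()`, rows of type `gene` only;
strand parsed and ignored — window membership is strand-agnostic).
`geneCountsPerWindow()` counts class members whose interval intersects
the ±1`sigma` window interval; a gene spanning two windows counts in
both, because the statistic is a per-window density, not a partition.
Membership is by any interval overlap rather than gene midpoint: genes
are counted "in" a window whenever they touch it.

`enrichmentPermutationTest()` compares the mean class count in
high-diversity windows against the rest, with a null built by permuting
the high/not-high labels without replacement (class sizes preserved),
1000 permutations by default. The p-value counts null differences
**greater than or equal to** the observed one, with the add-one
correction — a deliberate, conservative deviation from a strict
"greater than" count, which produces p = 0 pathologies on degenerate
data (e.g. all-zero counts). When the number of distinct labelings is at
most 100,000 the null is enumerated exhaustively and the p-value is the
exact tail proportion. `annotateRegions()` inventories genes per merged
region with class densities per Mbp, and `sharedCandidates()` partitions
per-group candidate sets into exact Venn cells.

## The synthetic-data generator

No public accession provides the original raw data at desk scale, so the
package ships a generator (`simulateDataset()`) whose planted truth makes
every stage falsifiable. It is genealogy-free by design — the claims
under test concern the scan, not demography — and works per locus:

1. A virtual pool of fully linked sequences receives
   `Poisson(theta * L * a1)` mutations; each site's derived allele is
   carried by a contiguous block (of the site's derived count) of one
   fixed random circular ordering of the pool — a crude stand-in
   genealogy that preserves per-site frequencies exactly while creating
   the within-tag linkage a non-recombining 92-bp locus really has.
   Under the neutral mode, derived counts follow the 1/k spectrum, so
   expected pairwise diversity equals `theta` exactly; the
   "intermediate" mode draws site frequencies from Beta(20, 20)
   (concentrated at 0.5), which yields positive Tajima's D.
2. The pool's distinct haplotypes and their frequencies `q` parameterize
   a multiallelic Balding–Nichols model: each population draws allele
   frequencies from `Dirichlet(((1 - F)/F) q)` with
   `F = structure_Fst`, so haplotype-level F\_ST equals the divergence
   parameter in expectation (the tests verify recovery within ±0.05 at
   5,000+ loci). An earlier independent-site formulation was rejected
   exactly because it broke within-locus linkage and made haplotype-level
   F\_ST systematically undershoot the parameter.
3. Individuals draw two alleles from their population's frequencies; the
   second is an identical-by-descent copy of the first with probability
   `inbreeding_F`, so complete selfing gives H\_o = 0 at every locus and
   H\_o declines monotonically in F. Missingness is whole-locus per
   individual (Bernoulli), matching RAD presence/absence filtering — no
   partial within-locus missingness.
4. Planted regions (non-overlapping intervals) multiply `theta`, shrink
   the divergence parameter by `fst_multiplier`, and may switch the
   frequency mode; a locus belongs to a region when its start coordinate
   falls inside. Genes are laid on a regular grid and labelled
   `candidate` with probability `p_in` inside planted regions (by gene
   midpoint) and `p_out` outside; a `control` class is assigned at
   `p_out` everywhere.
5. SNP records are exactly the segregating sites of the simulated loci,
   so the haplotype table, VCF, GFF3, class table, truth table and BED of
   planted regions are mutually consistent and round-trip through the
   package's readers. All randomness flows from the config seed with
   per-chromosome sub-streams; identical configs give byte-identical
   outputs.

Default study conditions: 92-bp tags at 12 kbp mean exponential spacing,
eight outcrossing populations of four diploids in one sample group,
background per-bp diversity 0.008 (an outcrossing *Arabidopsis*-like
level), divergence parameter 0.1 among populations, 20% missingness —
the regime the real scans of this kind operate in (groups of 17–35
individuals, 7,000–17,000 loci after filtering). What the generator does
**not** emulate: linkage between neighbouring loci (inter-locus values
are independent, so the bootstrap null is exactly calibrated here but
will be anti-conservative on strongly autocorrelated real genomes),
sequencing error and allele dropout, copy-number variation and paralogy,
and realistic demography (bottlenecks can mimic positive D). Passing
tests therefore demonstrate that the machinery recovers planted truth
under its stated model, not that real-data calls at these thresholds are
immune to those confounders.

## Numerical and design choices

* Quantile selections use nearest-rank thresholds with ties included
  (a small epsilon guards `ceiling()` against floating-point fuzz); only
  the top-D selection trims to an exact `round(q n)` size by genomic
  order, because its published percentages imply an exact denominator.
* Bootstrap tie comparison uses a relative 1e-9 tolerance so degenerate
  pools (all values equal) give p = 1 rather than coin-flip behaviour.
* Interval containers are `GRanges` (1-based closed) everywhere inside
  the package; GFF3 (1-based inclusive) and BED (0-based half-open)
  conversions happen only in the readers/writers, which keeps a single
  conversion point per format.
* Negative F\_ST estimates are never clipped internally.
* Undefined values are explicit: D with `S = 0` or `n < 4`, F\_ST with
  fewer than two populations with data, per-individual H\_o with zero
  genotyped loci all return flagged `NA` rather than 0.
* Problem sizes in the shipped tests are chosen to exercise the
  asymptotics that matter (10,000+ loci for null calibration, 5,000+ for
  F\_ST recovery, 10 replicate genomes for planted-truth recovery) while
  a full suite run stays in the minutes range; bootstrap replicates scale
  down accordingly and every scaled size is stated where it is used.

## A worked miniature

```{r example, eval = FALSE}
cfg <- simConfig(
  n_chromosomes = 1, chrom_length = 4e6, seed = 13,
  planted_regions = list(list(chrom = "chr1", start = 1e6, end = 1.8e6,
                              diversity_multiplier = 5, fst_multiplier = 1,
                              frequency_mode = "neutral")))
sim <- simulateDataset(cfg)
sc <- scanConfig(sigma = 60000, boot_reps = 2000, seed = 21)
res <- runPipeline(sim$haplotypes, sc, snps = sim$snps, genes = sim$genes,
                   chrom_lengths = sim$truth$chrom_lengths)
res$summary
```

The summary reports the window categories (He only, pi only, both — they
always sum to the significant total), the proportion of significant
windows, merged region count and span, and the top-D overlap. On planted
data the significant windows concentrate inside the planted interval and
the candidate-class enrichment p-value is small, while the control class
shows none; on null data the significant proportion sits at the alpha
level. The acceptance script (`scripts/acceptance.R`) recomputes these
from scratch at fixed seeds.

## Known limitations

Beyond the generator caveats above: the bootstrap null treats loci as
exchangeable genome-wide, so chromosomes with systematically different
diversity would need a stratified pool; the Tajima's D missing-data rule
(median per-site n) is one of several defensible choices; and the scan's
spatial resolution is bounded by `sigma` — with 900 kbp windows in
low-polymorphism selfing groups, a "region" is a neighbourhood, not a
gene. Pairwise F\_ST between a population and itself is ~0 only in
expectation; small groups give noisy, occasionally negative estimates by
construction.
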