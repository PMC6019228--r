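---
title: "Models and methods behind miniscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind miniscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miniscan)
```

miniscan implements the computational arms of a selection-signature and
body-size study design used for miniature pony breeds: a handful of
whole-genome-sequenced cases against a pooled control panel, followed by a
genotyped validation cohort for the candidate loci. This vignette explains
each model, its assumptions, the tunable parameters, and the choices made
where the design was genuinely open. Every empirical number quoted here is
computed by the package's tests, the `analysis/` scripts, or
`scripts/acceptance.R`.

## Runs of homozygosity

`call_roh()` is a two-pass, PLINK 1.07-style scan. Pass one slides a window
of `window_snps` (default 50) consecutive SNPs along each chromosome; a
window is *homozygous* when it contains at most `max_het_per_window`
(default 3) heterozygous and `max_missing_per_window` (default 10) missing
calls. Each SNP is flagged homozygous when the fraction of windows
overlapping it that are homozygous reaches `window_hit_threshold`. Pass two
takes maximal runs of flagged SNPs, splits them wherever consecutive SNPs
lie more than `max_gap_bp` (default 100 kb) apart, and keeps runs with at
least `min_snps` (50) SNPs, at least `min_length_bp` (150 kb), and a mean
SNP spacing of at most `max_kb_per_snp` (3) kb — the density rule is
interpreted as a segment-level mean, not a local one.

Two parameters deserve comment:

* `window_hit_threshold` defaults to 0.05, the PLINK default. The scan
  parameters above map onto PLINK's `--homozyg-*` flags, and unstated ones
  take PLINK defaults. The threshold only matters at segment edges: with
  0.05 and 50-SNP windows, roughly two SNPs at each end of a clean tract
  fail the vote, so called boundaries sit a few SNPs inside the true tract.
  On tracts of 300 kb and realistic SNP density this costs well under 10%
  of reciprocal overlap (the recovery tests require at least 90%).
* In the *zero-tolerance regime* (`max_het_per_window = 0`,
  `max_missing_per_window = 0`, `window_hit_threshold` near 0) the window
  vote reduces exactly to "SNP lies in a maximal homozygous run of at least
  `window_snps` SNPs", so the caller must agree segment-for-segment with a
  brute-force enumeration of maximal runs. The test suite exploits this for
  an exact oracle-equivalence check; end-of-chromosome window handling,
  which differs subtly between PLINK versions, is thereby covered by a
  regime where it provably cannot matter, and the default regime is tested
  via recovery rates instead of exact equality.

`shared_regions()` intersects per-sample segments at base-pair resolution:
a position belongs to a shared region only if *every* required sample
covers it with some ROH segment. `genome_fraction()` is merged coverage
over total genome length.

## Dating selection from ROH length

A haplotype block inherited identical-by-descent from a common ancestor `g`
generations ago has expected recombination-eroded length of order `1/g`
Morgans on each side; the package uses the standard point estimate
`generations = 1/(2c)` for a tract of recombination length `c` Morgans.
With a uniform genetic map (default 1 cM/Mb, configurable via `cm_per_mb`),
`c = length_Mb / 100`. Years use a fixed generation interval, default 10
years as is conventional for horse populations:

```{r}
date_roh(c(2.522687, 0.278201))
```

The estimate assumes a uniform map and a single ancestral haplotype; it is
a point estimate with broad sampling variance, so reported ages should be
read as orders of magnitude ("tens vs hundreds of generations").

## Windowed Fst

`windowed_fst()` uses the Hudson estimator with finite-sample corrections.
Per SNP, with allele frequencies `p1, p2` from non-missing genotypes and
allele counts `n1, n2`:

```
N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)
D = p1(1-p2) + p2(1-p1)
```

and a window's Fst is the *ratio of averages* `sum(N)/sum(D)` over its
SNPs. The Hudson form is chosen deliberately for its robustness to very
unequal sample sizes (3 cases against a pooled panel of 24); `N <= D` holds
per site, so window estimates never exceed 1. Negative estimates are
reported as-is — clamping at zero would distort the empirical percentile
that the scan thresholds on. Windows default to 50 kb spans advancing in
10 kb steps from position 1 of each chromosome; windows without an
informative SNP carry `NaN` and are excluded from `top_percentile()`, whose
threshold is the empirical quantile with linear interpolation.

Two statistical points:

* Overlapping windows share 80% of their SNPs with each neighbour, so
  their values are strongly autocorrelated. Null-calibration checks
  ("mean window Fst within 3 SE of 0") therefore use non-overlapping
  tilings, where the iid standard error is the right one; the overlapping
  tiling remains the default for scanning, where resolution, not
  independence, is the goal.
* Sites are skipped when either group has fewer than two observed alleles;
  the per-site components are unbiased under binomial sampling (verified by
  simulation in the test suite's null checks).

The count of "top regions" is reported two ways — raw selected windows and
maximal merged runs of them (`merge_selected_windows()`) — because both
conventions are in use and they differ numerically.

## Variant screening in shared ROH regions

`screen_variants()` composes three deliberately simple filters: position
inside a shared region (1-based, inclusive at both ends), predicted effect
class in {HIGH, MODERATE} from a consumed annotation table (effect
prediction itself is upstream and out of scope), and the exclusivity
pattern — *every* case homozygous for the alternate allele, *every* control
homozygous reference. Missing calls disqualify a variant rather than pass
it: in a candidate screen, a false positive costs a validation assay while
a false negative merely stays in the long list. Samples of unclear
phenotype (e.g. ancient genomes) can be excluded from both groups before
testing. SIFT-style deleteriousness (score < 0.05) is carried as metadata
rather than enforced, mirroring a two-route screen (deleterious-and-novel
versus exclusive-genotype) in which the routes are filtered differently;
the genotype pattern itself is configurable (`case_code`, `control_code`)
because the treatment of heterozygous cases in the deleterious route is a
genuinely open design point.

## Read-depth copy-number detection

`log2_ratios()` computes, per fixed window,
`log2(((case + 0.5)/(control + 0.5)) * (total_control/total_case))`. The
0.5 pseudocount keeps the ratio defined exactly where it matters most —
zero-count windows inside homozygous deletions. Windows are fixed-width
(default 500 bp) and non-overlapping; a read-count-derived window size
could be substituted upstream, but a fixed grid keeps the statistics of
planted-truth experiments transparent. Note one consequence of total-count
normalization: a CNV occupying a large fraction of the analysed territory
shifts all other windows' ratios, so tracks should cover much more genome
than the events they are meant to detect.

`call_cnvs()` reports maximal runs of at least `min_windows` (10)
consecutive windows whose values all sit at or beyond the log2 threshold
(0.7) in the same direction. Runs are strictly consecutive — a single
sub-threshold window ends a run, which is stricter than tools that bridge
small gaps; with the default 10-window minimum this trades a little
sensitivity to noisy heterozygous losses for exact reproducibility. Each
run's p-value combines per-window Geary–Hinkley transforms of the count
ratio (a normal approximation for the ratio of two Poisson counts under
the null of equal relative coverage) using Stouffer's method, and calls
with `p >= alpha` (0.001) are dropped. `classify_zygosity()` bands the mean
log2 ratio: at or below −2.5 homozygous loss (a pooled case group with all
carriers deleted drives counts to ~0), between −1.5 and −0.7 heterozygous
loss (log2 of 1/2 is −1), at or above 0.7 gain, otherwise ambiguous.

`intersect_cnvrs()` reduces each pairing's calls, takes the base-pair
intersection across all pairings per direction, and keeps pieces of at
least `min_overlap_bp` (50). Direction must agree across pairings — a
region cannot be a loss against one control panel and a gain against
another and still be a coherent case-specific copy-number region.

## Genotype–trait association

`fit_single_locus()` is a one-way fixed-effects linear model with genotype
as a categorical factor — R², F with (k−1, n−k) degrees of freedom,
p-value, and least-squares means with pooled-residual standard errors. In
a one-factor layout the least-squares means equal the class means; the
categorical coding also absorbs non-monotone patterns (a heterozygote
class falling below both homozygotes) without forcing them into an
additive slope. No random terms are fitted: the target statistics are
fully determined by the fixed-effects model.

`fit_joint_additive()` regresses the trait on the allele counts of several
loci simultaneously, with optional dominance indicators per locus
(`dominance_for`), and summarizes the architecture by
`total_reduction_cm = |2 * sum(a_k)|` — the expected difference between an
individual homozygous wild type everywhere and one homozygous mutant
everywhere. Dominance support is per-locus because fitting dominance for
all loci versus only the one that shows it are both defensible; the
default fits none.

`ld_r2()` is the squared Pearson correlation of 0/1/2 allele counts over
complete pairs, invariant to swapping reference and alternate coding.
`miniature_classifier()` encodes the four-locus synergy rule — positive
when homozygous mutant at all four loci, or at three with the fourth
heterozygous — which holds for exactly 5 of the 81 possible genotype
combinations; `ceiling_check()` tests a height ceiling (default 87 cm)
empirically against classifier-positive animals.

## The synthetic-data generators

`simulate_genotypes()` draws each sample's genotype at each locus
independently as Binomial(2, freq), with background frequencies uniform on
[0.05, 0.95], planted autozygous tracts forced homozygous, and divergent
intervals giving cases and controls different frequencies. Loci carry no
background linkage disequilibrium: every downstream stage is tested
against planted truth, and LD realism adds nothing to those checks while
obscuring them. Consequences worth knowing: background "homozygosity by
chance" can extend a called ROH slightly beyond a planted tract (real
flanking haplotypes would too), and null Fst windows are exchangeable,
which real linked windows are not. Passing tests on these populations
demonstrates correctness of the algorithms under their stated models, not
performance on real genomes with LD, mapping artefacts, or GC-dependent
coverage.

`simulate_read_depth()` draws control windows as Poisson(lambda) (default
lambda = 50 reads per window) and case windows as Poisson(lambda * cn/2)
inside planted events, with partially overlapped windows taking the
coverage-weighted rate so breakpoints fall inside windows, not on their
edges.

`simulate_cohort()` models the genotyped validation cohort — 243 animals
by default — as a 50/50 mixture of two strata: a miniature-type stratum
with mutant-allele frequency 0.85 at all four loci and a standard/related
stratum at 0.35. A mixed validation panel really is stratified by breed
type, and the mixture reproduces two of its signatures without any extra
machinery: excess homozygosity relative to Hardy–Weinberg at each locus,
and weak positive inter-locus allele-count correlation (r² around
0.1–0.25) of the magnitude seen between size loci in such panels. Trait
values follow `mean + sum a_k (g_k - 1) + sum d_k [g_k = 1] + noise`, with
defaults a = (−2.0, −1.5, −3.0, −2.74) cm per allele (full
homozygote-to-homozygote span 18.48 cm), no dominance, residual sd 3 cm,
and an all-heterozygous baseline of 98 cm, placing the opposite
four-locus homozygotes near 107 and 89 cm. The architecture is purely
additive: it does not itself enforce a height ceiling, so
ceiling-consistency demonstrations use a lower baseline (e.g. 90 cm),
under which every classifier-positive class sits beneath the 87 cm cap.

Reproducibility: each generator consumes an explicit integer seed; the
`sim_config()` master seed feeds fixed per-generator offsets (+1
genotypes, +2 traits, +3 read depth), so the same configuration always
yields bit-identical populations.

## Numerical and testing choices

* All internal coordinates are 1-based and inclusive; conversion to BED's
  0-based half-open convention happens only in `write_bed()`/`read_bed()`.
* Quantiles use R's default type-7 linear interpolation.
* Problem sizes in the routine checks are chosen to keep the full suite
  fast while leaving no property under-sampled: 2 Mb chromosomes with
  ~2000 SNPs for ROH recovery (100 replicates), 1000 non-overlapping
  windows for the Fst null, 100 Poisson replicates for the two planted
  deletion sizes (7245 and 21284 bp at 500 bp windows), and 200 cohort
  replicates for the joint-model span.
* Degenerate inputs fail loudly: empty case groups, single-genotype-class
  loci, rank-deficient joint designs, zero-length tracks and out-of-range
  scores all raise errors rather than propagate.

## Known limitations

* The ROH scan is genotype-based; it does not model genotyping error
  beyond the per-window heterozygote/missing allowances and performs no
  phasing or IBD-based inference.
* The Fst estimator operates on called genotypes; genotype-likelihood
  methods for low-coverage data are out of scope.
* CNV calling assumes Poisson counts on a fixed grid; overdispersed or
  GC-biased coverage would need upstream correction, and run-bridging
  across single noisy windows is deliberately not done.
* The 1/(2c) age is a point estimate under a uniform map.
* The association models fit no kinship or population-structure terms;
  in a stratified cohort the additive estimates include the between-
  stratum component, which is also true of the design they emulate.
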