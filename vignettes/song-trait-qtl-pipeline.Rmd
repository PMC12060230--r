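---
title: "Mapping courtship-song trait differentiation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping courtship-song trait differentiation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

songqtl implements a complete analysis pipeline for quantitative courtship
song traits measured on panels of *Drosophila melanogaster* strains: two
wild-derived population samples (France and Zambia) and a panel of
recombinant inbred lines (RILs) derived from one parental strain of each
population. This vignette is the package's own account of the statistical
methods, the tunable parameters, the synthetic-data generators used for
validation, and the design choices made where the design was genuinely
open.

## Recording-level data and filtering

The unit of observation is one 30-minute recording of one male courting a
female. Automated song segmentation yields 37 per-recording traits
(counts/min, durations in seconds, carrier frequencies in Hz, transition
probabilities and ratios in [0, 1], amplitudes in arbitrary units), plus
two quality fields: seconds of song per minute and total seconds of sine
song.

`filter_recordings()` applies two exclusion rules: recordings with less
than `min_song = 1` second of song per minute carry too little signal to
measure traits, and recordings with more than `max_sine = 55` seconds of
characterised sine song indicate a recording-equipment failure. Both
thresholds fire on strict violation only, so boundary values are retained.
The sine threshold is applied per recording (its natural reading for
30-minute assays); both thresholds are arguments, so a per-minute variant
is a one-line change if your assay duration differs.

`strain_trait_means()` collapses retained recordings to one row per
strain. Zeros are treated as "unmeasured" *per trait* — the segmentation
software emits zero when it failed to quantify a trait — so a recording
can contribute to some traits and not others; a strain × trait cell is
missing only when no replicate qualified. Missing values always propagate
as missing, never as zero.

## Population comparison and the family-wise min-p correction

Each trait is compared between populations with a two-sample Mann–Whitney
test (`mw_test()`): exact doubled-tail p-values when there are no ties and
the groups are small, otherwise mid-ranks with a tie-corrected,
continuity-corrected normal approximation — the standard two-sample
Wilcoxon behaviour, and verified against both `stats::wilcox.test()` and
full enumeration in the test suite.

Testing 37 correlated traits requires a family-wise correction that
respects the correlation structure. `familywise_fpr()` implements a min-p
(Westfall–Young style) permutation design: in each of `n_perm = 10000`
permutations the strain labels are reshuffled once into groups of 10 and
7, the *same* relabelling is applied to every trait, and the minimum raw p
across traits is recorded. A trait's corrected false-positive rate is the
proportion of permutations whose minimum p is at or below the trait's
observed raw p — the probability of seeing at least one p-value that small
anywhere in the family by chance. The shared-relabelling reading is the
one that makes "chance of at least one raw p-value this small" a
well-defined family-wise quantity; per-trait independent shuffling remains
available via `shared = FALSE`. Corrected rates are plain proportions
(they can be zero); `add_one = TRUE` switches to the (b+1)/(n+1)
convention. Because the permutation loop evaluates on the order of 10^5
Mann–Whitney tests, the implementation precomputes per-trait mid-ranks
(invariant under relabelling) and a U → p lookup table for the tie-free
exact case.

Calibration is checked, not assumed: on 200 null panels (no population
shift, correlated traits) the family-wise rejection rate at nominal 0.05
must fall inside the binomial 95% interval. The procedure is mildly
conservative because Mann–Whitney p-values at n = (10, 7) are discrete and
ties between observed and permuted minima count against rejection.

## Qst and the per-SNP Fst distribution

`qst()` decomposes strain trait means into between- and within-population
variance by method of moments with the standard unbalanced-design
correction. For panels of fully inbred strains the among-strain variance
within populations already includes (approximately twice) the additive
genetic variance, so the inbred form Qst = V_b / (V_b + V_w) is the
default; the outbred form V_b / (V_b + 2 V_w) is available via `form`.
Negative between-population variance estimates truncate to zero, so
Qst ∈ [0, 1].

`qst_fst_quantile()` places an observed Qst within an empirical per-SNP
Fst distribution as 100 × (# Fst < Qst)/N. The package computes Fst with
the Hudson-form estimator (`site_fst()`): numerator
(p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1), denominator
p₁(1−p₂) + p₂(1−p₁). The Hudson form is robust to small and unequal
samples, which matters because the comparison deliberately matches allelic
sample sizes to the phenotyped strain counts (10 and 7) via the
downsampling arguments of `panel_site_fst()`. Sites monomorphic for the
same allele in both samples have a zero denominator, are flagged
undefined, and are excluded from window summaries; small negative values
at undifferentiated sites are left untruncated.

## Additive QTL scan over ancestry windows

RIL genotypes are parental-ancestry dosages (0/1/2 copies of one parent's
ancestry) over ordered genomic windows (`ancestry_panel()`). Because some
ancestry classes are rare in many windows, the scan fits an additive
model: ordinary least squares of the trait on dosage, giving
LOD = (n/2)·log₁₀(RSS₀/RSS₁) = −(n/2)·log₁₀(1−R²) per window. Missing
dosages are dropped pairwise per window (panel missingness is low;
imputation would add model assumptions the scan does not need). Windows
where the panel-wide ancestry proportion of either parent strictly exceeds
0.90 are masked out of the scan entirely
(`mask_skewed_windows()`); windows with a single genotype class present
score LOD 0 with a warning.

Genome-wide significance uses phenotype permutations
(`perm_threshold()`): the trait vector is shuffled across RILs (strain
means, not replicate-level data), the full scan is rerun, and the maximum
LOD per permutation is recorded; the threshold is the empirical
1 − α quantile (type-7) of the maxima, and a peak's genome-wide p is the
proportion of permutation maxima at or above it. All arms are scanned
jointly so one threshold per trait controls genome-wide error. For
complete data the scan is a single standardised cross-product, so a
500-permutation threshold on a 305 × 500 panel takes well under a second.

Effect sizes (`qtl_effect_size()`) are reported as the fitted homozygote
contrast |2β̂| over the observed parental difference — "the proportion of
the parental strain difference explained" — with the signed direction
separate. Estimates at traits with several linked QTLs can be inflated by
linkage; the package reports the point estimate and leaves multi-QTL
modelling out of scope.

## Peak definition: merging, inclusive and restrictive CIs

A raw LOD landscape can be ragged, and deciding which local peaks
constitute one QTL needs explicit rules (`find_qtl_regions()`):

1. **Runs** (`significant_regions()`): maximal runs of consecutive
   unmasked windows with LOD ≥ threshold. Runs may span the centromere
   between two arms of one chromosome (window adjacency, not arm identity,
   is the unit; `adjacency = "arm"` changes that), never two chromosomes.
2. **Merging** (`merge_regions()`): two neighbouring runs merge when the
   minimum LOD over the valley strictly between them exceeds the shorter
   peak's maximum minus 1.5 — a 1.5-LOD support interval for the shorter
   peak would include the taller one. Applied left to right and iterated
   to a fixed point; a valley consisting only of masked windows merges
   vacuously.
3. **Confidence intervals** (`confidence_intervals()`): within a region,
   qualifying windows have LOD strictly greater than the region maximum
   minus 1.5. The *inclusive* CI is the contiguous span from the leftmost
   to the rightmost qualifying window (it may contain sub-cutoff
   windows); the *restrictive* CI is the possibly noncontiguous set of
   maximal qualifying runs — the sub-peaks most likely to contain the
   causative locus, and the intervals fed to the population-genetic
   screen. Masked windows inside a region bridge rather than break a
   restrictive run, consistent with the extension rule below. Ties at the
   maximum resolve to the leftmost window.
4. **Extension through masked windows** (`extend_through_masked()`): a CI
   whose boundary abuts a masked stretch extends across it; the first
   unmasked window beyond the stretch either qualifies (it is included
   and extension continues) or ends the CI and is excluded, leaving the
   bridged stretch inside the inclusive CI. A stretch running to the
   chromosome end extends the CI to the end with a warning.

All "greater than" comparisons in the merge and qualification rules are
strict. One open reading was whether an inclusive CI may extend into
flanking sub-threshold windows whose LOD is within 1.5 of the maximum; the
strict within-run reading is implemented (support intervals live inside
significant runs, except where masked-window extension applies).

## Residual mapping of correlated traits

When two correlated traits have overlapping QTLs, `residualize()`
regresses the lower-LOD (secondary) trait on the higher-LOD (primary)
trait over pairwise-complete RILs and returns residuals — the secondary
variation not explained by the primary. Residual traits then reuse the
*full* pipeline, including a fresh permutation threshold, because the
residual trait's null distribution differs from the original's. If the
two maxima are exactly tied the primary designation is an explicit
analysis choice. In simulation, a shared QTL whose effect on the
secondary trait is fully mediated by the primary drops below the
genome-wide threshold after residualisation, while an independently
planted QTL is retained (both at ≥90% over 100 replicates in the
acceptance suite).

## Windowed differentiation statistics and outlier windows

Over the restrictive CIs (or any window set), `popgen_window_stats()`
computes three statistics per window from two haplotype panels:

- **Fst_FullWin**: Hudson Fst over all variable sites in the window,
  ratio-of-averages (Σ numerators / Σ denominators) — standard practice
  and stable for low-frequency sites.
- **Fst_MaxSNP**: the maximum defined per-site Fst in the window. This is
  exactly the max over `site_fst()` values; note the full-window
  ratio-of-averages is *not* bounded by it in either direction.
- **χ_MD** (comparative haplotype identity): for each haplotype pair
  within a population, the span in bp of the longest run of sites at
  which the pair is identical (first to last site of the run; a
  single-site run spans the midpoints to its flanking usable sites; sites
  missing in either haplotype break no run but contribute no length).
  The population score is the mean over pairs, and χ_MD is the ratio of
  population 1's score to population 2's, with population 1 the putatively
  selected (non-ancestral-range) population — a configurable orientation.
  Pairs with more than half the window's sites unusable are dropped. A
  zero denominator yields an infinite sentinel with an `undefined` flag.
  The statistic is a reimplementation: the run-span accounting above is
  this package's documented definition, chosen so that a pair broken at
  the window midpoint halves the score (reciprocal ratios multiply to 1,
  and the statistic is invariant to haplotype order and global allele
  relabelling). The inner pairwise loop is compiled (Rcpp).

`arm_outliers()` ranks each statistic within its chromosome arm
(arm-wide, not restricted to QTL windows) and flags windows at or above
the empirical 1 − q quantile (type-7), q = 0.01 by default. With all
values tied every window reaches the quantile and all are flagged — the
documented degenerate behaviour. A window is an outlier window if flagged
for any of the three statistics.

## Gene annotation

`window_gene_links()` associates genes with windows: a gene links if a
qualifying exon overlaps the window (half-open intersection after
normalising GFF3's 1-based closed coordinates), or if a qualifying exon is
the first exon strictly to the left or right of the window — capturing
potential regulatory regions. `mode = "any_exon"` (coding or noncoding)
is used for general QTL annotation; `mode = "coding_exon"` for
differentiation-outlier windows. Nearest-distance ties link all tied
genes; strand is carried but never conditions the rules; overlapping and
flanking links are both reported with distinct types, so callers can apply
either reading of "nearest". `flag_candidates()` marks linked genes
against curated lists (e.g. male-mating-behaviour, wing-development,
nervous-system sets supplied as one-id-per-line files) and flags genes
linked to any outlier window.

## Synthetic data: what it emulates, and what it does not

All validation runs on generators with known ground truth
(`sim_ril_panel()`, `sim_ril_traits()`, `sim_population_panel()`,
`sim_haplotypes()`, `sim_gene_models()`, `sim_recordings()`). Every
generator is a pure function of its arguments and a seed. The default
conditions are fixed once:

- **RIL panel**: 305 RILs; five arms at approximate release-5.9 lengths
  with 100 windows per arm (500 genome-wide). Ancestry breakpoints form a
  Poisson process with rate g·c (g = 12 intercross generations,
  c = 2 cM/Mb), giving megabase-scale tracts; tract ancestries alternate
  from a fair start; residual heterozygosity is applied per tract at rate
  0.5⁵ after 5 generations of inbreeding. This is a Markov/Poisson
  approximation, not a pedigree simulation: it reproduces tract scale and
  dosage balance but not pedigree-level identity between RILs. Simulated
  windows are ~230 kb — much wider than the ~5 kb, 2,500-SNP-difference
  ancestry windows of a real panel — keeping the window count at the scan
  size used throughout while preserving the tract ≫ window scale
  relationship the masking and CI rules assume.
- **RIL traits**: a planted QTL's homozygote contrast is a stated
  fraction of the parental difference (the headline condition plants
  2β = 0.42·Δ on the slow-pulse-ratio scale, parents 0.745 and 0.833);
  19 replicates per RIL with replicate SD 0.15 and strain-level SD 0.02,
  so the strain-mean noise SD is ≈ 0.04 — chosen as realistic for a
  ratio trait whose population panels show strain SDs of 0.07–0.13. A
  heavy-tailed replicate option (scaled t₃) exists because permutation
  procedures should be, and are, insensitive to skewed replicate noise.
- **Population panels**: 10 vs 7 strains, 37 traits, AR(1) trait
  correlations with ρ = 0.5 (traits measured from the same recordings are
  correlated in blocks; AR(1) is a simple stand-in with the right
  qualitative structure), unit between-strain SD, and a per-trait shift δ
  (δ = 0 is the calibration null).
- **Haplotype panels**: Balding–Nichols divergence with F = 0.2 and
  20 + 20 haplotypes over 200 windows × 40 SNPs (a desk-scale stand-in
  for 197 and 96 genomes); sweeps are planted by copying one template
  haplotype with per-site error 0.02 within one window.

Passing tests on these generators show that the estimators and algorithms
recover what was planted under the stated statistical structure. They do
not show robustness to features real data have and the generators lack:
assay-day effects, inversion polymorphism and recombination-rate
variation, linked selection outside the planted window, genotyping error
in ancestry calls, or non-Gaussian strain effects.

## Numerical choices and known limitations

- Permutation thresholds use the type-7 empirical quantile; genome-wide
  p-values are plain proportions of permutation maxima.
- LOD is computed from correlations with a guard for zero-variance
  columns; the identity LOD = −(n/2)log₁₀(1−R²) is asserted against
  independent OLS algebra to 1e-10 in the tests.
- The acceptance experiments use 500 permutations (calibration) and 300
  permutations (recovery) per scan, 200 null replicates and 100 recovery
  replicates — sizes at which binomial Monte-Carlo error is small relative
  to the tolerances checked, and chosen as the package's standing
  validation sizes.
- The per-site Fst estimator conditioned on variable sites carries a
  small (~0.005 at F = 0.2) downward bias in window means relative to the
  nominal Balding–Nichols parameter; the consistency check uses an
  absolute ±0.02 band around F.
- Out of scope by design: audio processing and song segmentation,
  ancestry-HMM genotyping, multi-QTL/epistasis models, X-specific dosage
  models, phasing, inversion handling, GO enrichment statistics, and live
  database queries. Reproducing the published strain-level numbers
  requires the original recording-level dataset, which is not
  redistributed here; the acceptance suite documents how to point the
  package at a local copy.
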