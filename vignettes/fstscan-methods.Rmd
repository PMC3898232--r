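---
title: "Methods: multi-population Fst scans for selection signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-population Fst scans for selection signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstscan)
```

## What the package computes

`fstscan` detects candidate loci under selection in multi-breed SNP-chip
panels. The workflow is the classical outlier scan: estimate a per-SNP
fixation index (Fst) across populations, build the empirical genome-wide
distribution of those estimates, and declare loci in the extreme upper tail
candidates for (natural or artificial) selection. Around this core the
package provides PLINK PED/MAP input, sequential marker quality control,
merged-group pairwise contrasts, SNP-to-gene candidate mapping, population
structure PCA, and a fully synthetic data generator used to validate every
stage, since chip datasets of this design are frequently not deposited.

The default study conditions are a nine-breed domestic pig panel: six
Chinese indigenous breeds (TC, BM, LW, WZS, NX, LC), two European
commercial breeds (Landrace, Large White) and one developed breed (YT),
with sample sizes 35, 22, 23, 25, 24, 40, 18, 26, 22 (235 animals) and
tens of thousands of autosomal plus X-chromosome SNPs.

## The Fst estimator

Per SNP, Fst is estimated by the gamete-level nested ANOVA (the
Weir–Cockerham-type mean-squares formulation):

$$
F_{ST} \;=\; \frac{MSP - MSI}{MSP + (n_c - 1)\,MSI + n_c\,MSG},
$$

where MSP, MSI and MSG are the mean squares among populations, among
individuals within populations, and among gametes within individuals of a
two-level nested ANOVA on per-gamete allele indicators, and

$$
n_c = \frac{S_1 - S_2/S_1}{n - 1}
$$

corrects for unequal sample sizes ($S_1$ total sample size, $S_2$ sum of
squared group sizes, $n$ non-empty groups; for $n$ equal groups of size
$s$, $n_c = s$; for the nine default breed sizes, $n_c \approx 25.9053$).

The sums of squares have closed forms in the per-population allele
frequency $p_i$, observed heterozygote proportion $h_i$ and locus sample
size $s_i$:

$$
SSP = \sum_i 2 s_i (p_i - \bar p)^2,\quad
SSI = \sum_i \bigl(2 s_i p_i(1-p_i) - s_i h_i/2\bigr),\quad
SSG = \sum_i s_i h_i/2,
$$

with degrees of freedom $n-1$, $S_1-n$ and $S_1$, and $\bar p$ the
size-weighted mean frequency. The test suite checks this closed form
against a literal oracle that expands every individual into two 0/1 gamete
indicators and accumulates the nested sums of squares by explicit loops;
the two paths agree to machine precision ($<10^{-12}$, typically
$\sim10^{-16}$).

Key conventions:

* **Missing data.** $s_i$, $S_1$, $S_2$, $n$ and hence $n_c$ are
  recomputed per locus from non-missing calls; populations with no data at
  a locus are dropped and $n$ shrinks. Removing an individual that is
  missing at a locus cannot change that locus's estimate.
* **Undefined loci.** The estimate is undefined (reported `NA`) when the
  denominator is zero — the locus is monomorphic in the analysed sample —
  or when MSI has no degrees of freedom (every population a single
  individual). Undefined loci are excluded from summaries and from the
  empirical outlier distribution, and the defined count is always
  reported.
* **Negative estimates are retained.** Truncating at zero would distort
  the empirical distribution the outlier thresholds are computed from.
* **Allele choice does not matter.** Dosages count the lexicographically
  larger allele character (a determinism device, not a reference allele);
  the estimator is invariant to swapping the counted allele, which the
  suite verifies.
* **X-chromosome SNPs are treated as autosomal diploid** and flagged only
  by their chromosome label; heterogametic coding is out of scope.
* The per-scan summary reports the arithmetic mean and SD of defined
  per-locus estimates; a multilocus ratio-of-sums estimate (sum of
  numerators over sum of denominators) is also reported for reference but
  never used for thresholds.

Groupings map breed labels to populations. `all_pop_grouping()` treats
every breed as its own population; `merge_grouping()` pools breeds for
pairwise contrasts (e.g. Chinese indigenous vs European commercial, or a
Northern vs Southern contrast restricted to a breed subset). Every breed
must be assigned explicitly; an `NA` assignment excludes the breed from
that contrast. In the default Chinese-vs-European contrast the developed
breed YT is pooled with the Chinese indigenous group, since it was bred in
China from local stock; users can reassign it in one line of config.

## Quality control

Three marker filters run sequentially, each counted on the survivors of
the previous step — the only bookkeeping under which per-step removal
counts and the final total are mutually consistent:

1. unmapped markers (chromosome `"0"`/empty or position 0) are dropped;
2. markers with pooled minor allele frequency **strictly below** 0.05 are
   dropped (the pooled MAF ignores breed labels, matching standard PLINK
   behaviour; a marker at exactly 0.05 is retained);
3. markers genotyped in **strictly less than** 90% of individuals are
   dropped (exactly 90% retained).

Markers whose MAF is undefined because every call is missing pass the MAF
step and are caught by the call-rate step. Individuals are never removed.
Both thresholds and the unmapped toggle are exposed (`qc_config()`), and
QC is idempotent: a second pass removes nothing.

## Outlier calling

The threshold at quantile $q$ over $N$ defined estimates is the order
statistic of 1-based rank $\lceil qN \rceil$ — an element of the data, no
interpolation — and outliers are values **strictly greater** than the
threshold. With $N$ distinct values this selects exactly
$N - \lceil qN \rceil$ loci; for $N = 44{,}652$ and $q = 0.99$ that is 446
SNPs, the printed-count behaviour this convention uniquely reproduces.
Ties at the threshold reduce the count (possibly to zero), which is the
honest reading of "strictly greater". A guard of $10^{-9}$ is subtracted
inside the ceiling to protect against floating-point noise when $qN$ is an
exact integer. Thresholds are computed on the pooled genome-wide
distribution including the X chromosome; defaults report the 97.5% and
99% lines and call candidates at 99%, all configurable
(`scan_config()`).

Two diagnostics accompany the scan. `per_chromosome_track()` emits
mapped markers by chromosome with positions in Mb and flags attached — the
tabular content of a genome-scan plot. `fst_distance_correlation()` bins
same-chromosome SNP pairs by separation (default 50 kb bins to 1 Mb) and
reports the Pearson correlation of their Fst values, each pair entered
symmetrically; overflowing bins are uniformly subsampled with a seeded
generator (full pair enumeration is quadratic and pointless), and bins
with fewer than 10 pairs report `NA`.

## Gene mapping

A SNP belongs to a gene when its position falls in the annotated span
(UTRs, coding and introns) extended by a symmetric flank covering the
upstream/downstream regions. Upstream/downstream extents are never
well-defined constants, so the flank is a required, visible parameter
(default 5,000 bp) rather than a hidden one; assignment is monotone in the
flank and multi-gene assignment is allowed. Sub-features (UTR vs intron vs
exon) are deliberately not distinguished: span-plus-flank membership is
equivalent to the union rule and needs no transcript models. Interval
overlap is delegated to `IRanges::findOverlaps()` per chromosome.

The candidate report lists, per gene with at least one flagged SNP, the
flagged SNPs, their count, and the longest run of flagged SNPs that are
consecutive in genome map order among *all* markers — contiguous outlier
runs are a classic corroborating signal for a selective sweep. Genes sort
by outlier count descending, gene id ascending on ties. Flagged SNPs
assigned to no gene go to an intergenic overflow list so that per-gene and
intergenic counts conserve the total.

## Structure PCA

Genotypes are standardized per marker: missing calls imputed to the mean
dosage (zero contribution after centering), centered at $2\hat p$ and
scaled by $\sqrt{2\hat p(1-\hat p)}$ — the drift-scaled standardization
standard in population genetics, which puts loci on a common
drift-variance scale. Monomorphic and fully missing columns are dropped.
Scores come from the eigendecomposition of the individual-by-individual
cross-product; variance fractions are eigenvalues over the total, so they
sum to one over the full rank ($n-1$ after centering). Each component's
marker-loading vector is sign-flipped to have non-negative sum, making
output deterministic.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture: it defines the
conditions under which the estimator can be validated against ground
truth.

* **Model.** Ancestral frequencies are uniform on [0.05, 0.95]; each
  population draws its locus frequency from the Balding–Nichols beta
  distribution with drift parameter $F$ (default 0.2, matching the strong
  differentiation of long-separated breeds), so
  $\mathrm{Var}(p_i \mid p) = F\,p(1-p)$; genotypes are Binomial(2, $p_i$)
  (Hardy–Weinberg within breeds). The ANOVA estimator is consistent for
  $F$ under this model, giving a clean recovery target: at $F = 0.2$ with
  5,000 neutral loci the mean per-locus estimate lands within $\pm 0.02$
  of 0.2 (observed $\approx 0.193$; the small downward offset is the
  classical ratio bias of per-locus estimates, and the multilocus
  ratio-of-sums estimate is essentially unbiased).
* **Selected loci.** `plant_outliers()` either sets a near-fixed
  difference (0.98 vs 0.02) between a configurable group split (default:
  the European commercial pair against all others, emulating
  domestication/breeding divergence) or redraws with a boosted $F$.
  Planted loci never coincide with planted QC defects, so they always
  survive QC.
* **QC defects.** Unmapped markers get chromosome `"0"`/position 0;
  low-MAF markers are overwritten to pooled frequency ≈ 0.02; low-call-rate
  markers get just over 10% of calls masked. Defect classes are mutually
  exclusive by construction so QC removal counts are exactly predictable.
  For the same reason, neutral mapped markers whose *empirical* pooled MAF
  falls below 0.05 by sampling noise (unavoidable with ancestral
  frequencies near the boundary) are nudged up by flipping the minimal
  number of major-homozygote calls to heterozygous
  (`min_neutral_maf = 0.05`; set 0 to disable). There is no background
  missingness by default; real chips have both background missingness and
  genuinely low-MAF neutral loci, so real QC counts are not exactly
  predictable — only the planted-truth bookkeeping is.
* **LD blocks.** With `ld_block_size > 1`, loci in a block share one
  frequency draw plus N(0, 0.01) jitter, giving block-local correlation of
  Fst that decays past the block span — enough structure to exercise the
  distance-correlation diagnostic, not a realistic recombination map.
* **Layout and reproducibility.** Mapped markers are spread evenly over 18
  autosomes plus X (140 Mb each by default). All draws flow from one seed
  with fixed stream order (frequencies: seed; outlier placement: seed + 1;
  genotypes and defects: seed + 2), so identical configurations give
  byte-identical PED/MAP/truth output.

**What passing tests do and do not show.** The generator has no linkage
disequilibrium beyond the optional block mode, no ascertainment bias (SNP
chips are enriched for SNPs common in the discovery panels, which inflates
real-data mean Fst), no mutation/migration structure, and symmetric drift
across populations. Recovery of $F$, of planted outliers and of planted QC
defects therefore validates the estimator arithmetic and the scan
machinery — not the biological calibration of any real chip dataset.
Published results at this design's scale (e.g. a genome-wide mean Fst near
0.37 on a porcine SNP60 panel) reflect chip ascertainment and real
demography and are not reproduction targets for the simulator.

## Numerical and design choices

* Sums of squares are clamped at zero when floating-point noise drives
  them within $-10^{-12}$ of it; SSI is analytically non-negative.
* The quantile rank uses the $10^{-9}$ ceiling guard described above.
* Marker order is chromosome-numeric first, then non-numeric labels
  (X, …) alphabetically, unmapped last; positions are 1-based inclusive
  throughout (BED input converted on read).
* Half-called PED genotypes are an error, not silently missing — surfacing
  corruption beats masking it.
* PCA sign convention: loading sums non-negative. k-means label recovery
  in tests scores cluster purity (majority label per cluster).
* Pipeline logs are timestamp-free and the manifest contains no absolute
  paths, so identical config + seed reproduces outputs byte-for-byte.

Test problem sizes are chosen to exercise the study design at desk scale:
the full 235 × 45,652 pipeline (about 15 s), a 235 × 5,000 neutral
recovery run, and hundreds of randomized micro-datasets for the oracle
equivalence; the complete suite runs in about a minute.

## Known limitations

* **Three PCs cannot resolve nine equally diverged populations.** Under
  the symmetric island model the between-population variance spreads over
  $n-1 = 8$ near-equal eigendirections, so any 3-dimensional projection
  superimposes some of the nine clusters: k-means on PC1–PC3 recovers
  about 91% of labels at $F = 0.2$, while five or more components recover
  100%. High PC1/PC2 variance fractions in real breed panels reflect
  hierarchical divergence (e.g. a dominant Chinese/European split), which
  the symmetric generator deliberately lacks.
* Exact ties between per-locus estimates are possible (dosage counts are
  discrete); the strictly-greater rule then selects fewer than
  $N - \lceil qN \rceil$ loci. Tie frequency is about 0.2% of loci at
  study scale.
* The estimator treats X as autosomal; male hemizygosity is not modelled.
* No individual-level QC, Hardy–Weinberg filtering, relatedness pruning,
  haplotype statistics (EHH/iHS), or FDR-style calibration of the
  empirical thresholds.

## Worked example

```{r example, eval = FALSE}
cfg <- default_pipeline_config(seed = 1)
manifest <- run_pipeline(cfg, "scan_out")
manifest$qc$n_output               # 44652
manifest$groupings$ALLPOP$n_outliers  # 446 (all estimates distinct)
```
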