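---
title: "Methods: exercise-responsive lncRNAs and chromatin accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exercise-responsive lncRNAs and chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exlnc)
```

## The problem

Endurance-training studies in rodents profile many tissues from male and
female animals at several training durations (here: weeks 1, 2, 4 and 8),
with each trained group contrasted against sex-matched sedentary controls.
Long non-coding RNAs (lncRNAs) respond to such training in a strongly
tissue- and sex-specific way, and a natural question is whether a
training-responsive lncRNA is linked to local chromatin remodelling: does
an ATAC-seq peak near the lncRNA locus change accessibility with the same
temporal profile, and is that peak close to the promoter of a
protein-coding gene it might regulate in cis?

`exlnc` implements this analysis as a tested pipeline over four layers:

1. **Differential lncRNA sets** from per-contrast effect tables
   (log2 fold-change, p-value, mean FPKM per feature × tissue × sex ×
   week).
2. **Sex-combined peak significance**: Fisher's sum-of-logs over the male
   and female p-values, with Benjamini-Hochberg control within tissue
   strata.
3. **lncRNA–peak–gene triads**: local pairing, trajectory correlation and
   a distance-weighted activity score.
4. **Sequence features**: GC content, group tests, smORF discovery and a
   microprotein search database.

A seeded synthetic-data generator emulates the study design end to end, so
every stage is testable against known ground truth without any external
download.

## Differential sets

Two complementary schemes are implemented, applied after an expression
gate that keeps features with mean FPKM ≥ 1:

* **sensitive** (`call_differential`): raw p ≤ 0.01 and |log2FC| ≥ 1.
  This favours recall for low-abundance, variable transcripts such as
  lncRNAs.
* **stringent** (`call_differential_fdr`): Benjamini–Hochberg q ≤ 0.10
  (computed within tissue) and |log2FC| ≥ 0.5, trading recall for a
  high-confidence set.

All boundaries are inclusive; strict variants are available via
`strict = TRUE`. A member is a (feature, sex, week) cell; the per-tissue
unique-feature set is the projection of the members, and both counts are
reported because deduplication across sexes can be done before or after
thresholding each cell. Sex overlap is summarised as
`100 * |intersection| / |union|`, a symmetric and bounded choice of
denominator. Z-score trajectory summaries standardise each feature across
its cells (mean 0, sd 1, the expression-heatmap convention) before
averaging, because standardisation per feature is the only axis that makes
means comparable across features of very different abundance.

## Sex-combined significance

Male and female p-values for the same feature are combined with Fisher's
sum-of-logs, `x2 = -2(ln p_M + ln p_F)`, referred to the upper tail of a
chi-square distribution with 4 degrees of freedom. Inputs are floored at
1e-300 before the logarithm so underflowed p-values cannot yield infinite
statistics. Combined p-values are then adjusted by Benjamini–Hochberg
*within tissue strata* (`bh_adjust(p, strata)`), which preserves
per-tissue calibration while remaining a fully specified, dependency-free
procedure; every output that uses it is flagged `"bh_by_tissue"`.
Covariate-weighted FDR procedures that learn weights from the data are
deliberately out of scope. Where a downstream step needs "significant at
FDR < 0.05" for a feature, the default is the combined-then-adjusted
q-value; the raw per-sex scheme remains available through configuration.

## Master peak list and count filter

Peaks from all conditions are reduced to a master list by replacing each
peak with the 200-bp window centred on its summit (`half_width = 100`) and
merging overlapping or book-ended windows per chromosome
(`trim_and_merge_peaks`). The merged peak's summit is defined as the
midpoint of the merged interval — a deterministic, symmetric choice — and
a window that would extend below position 0 is clamped with a warning.
Merging itself is idempotent: `merge_peaks(master)` returns the master
list unchanged, which the tests assert; note that *re-trimming* a merged
cluster wider than 200 bp would necessarily shrink it, so idempotence is a
property of the merge, not of trim-plus-merge. For odd trim widths the
extra base falls on the right of the summit; with the even default this
never arises. Peaks are then kept when at least 10 reads are seen in 4 or
more samples, restricted to autosomes and sex chromosomes via a
configurable allow-list (`is_standard_chromosome` by default), so the
procedure is species-agnostic.

## Linking lncRNAs to chromatin

Two distances are deliberately different quantities:

* **Pairing distance** — between the *interval midpoints* of the lncRNA
  locus and the peak; pairs are kept within a ±500 kb window, boundary
  inclusive ("within" read as ≤).
* **Scoring distance** — between the *peak summit* and the nearest
  protein-coding *TSS* (interval start on `+`/unstranded genes, `end - 1`
  on `-` genes).

For each local pair the log2FC trajectories are correlated (Pearson) on a
fixed 8-point grid: male weeks 1, 2, 4, 8 followed by female weeks 1, 2,
4, 8 (`traj_columns()`). Concatenating the sexes uses every available
contrast and matches the sex-combined significance call; per-sex 4-point
vectors are a configurable alternative but give the correlation very few
degrees of freedom. Zero-variance trajectories are never silently scored:
their correlation is `NA`, a warning is counted, and the pair is excluded
downstream.

Triads attach the nearest coding TSS to each peak (ties broken by the
lexicographically smallest gene identifier), score
`activity = r / (distance + 1)`, keep pairs with r ≥ 0.5, and retain per
gene only the highest-scoring triad (ties by smaller TSS distance, then
lexicographic lncRNA id). The score keeps the sign of r, is bounded by
|r|, equals r at distance 0 and decreases strictly with distance, so it
ranks proximal, concordant associations first. Genes are labelled
up/down/ns from the differential coding-gene sets.

## The synthetic-data generator

`synth_config()` fixes the study conditions: 4 training weeks × 2 sexes,
and by default 200 lncRNAs, 300 coding genes and 1,000 peaks on two 20-Mb
chromosomes; 20% of features planted differential with |log2FC| mean 2
against trajectory noise sd 0.2; 20% of non-planted features below the
FPKM ≥ 1 gate; 5% of peaks planted below the count filter; 10% of lncRNAs
coupled to a peak within 50 kb. These sizes keep an end-to-end run in
seconds while leaving every gate non-trivially populated.

Design choices that matter for interpretation:

* **P-values are analytic, not refit.** Planted cells draw log2FC from
  `N(±effect, noise_sd)` and take `p = 2 * pnorm(-|log2FC| / noise_sd)`;
  null cells draw log2FC from `N(0, noise_sd)` and p independently from
  `Uniform(null_p_min, 1]`. The differential model itself (negative
  binomial count fitting) is out of scope — only the filter logic
  downstream is under test. `null_p_min = 0.1` reproduces the idealised
  separation regime (all planted p < 1e-4, all null p > 0.1) in which the
  sensitive filter must recover the planted set exactly.
* **Couplings live in trajectory space.** A coupled lncRNA–peak pair
  shares a latent 8-point trajectory with independent noise; the latent
  standard deviation is `noise_sd * sqrt(r / (1 - r))`, which makes the
  population correlation exactly `coupling_r` (and 1 in the noise-free
  limit). Coupled lncRNAs are drawn from the non-differential pool and
  keep null p-values: coupling is a statement about shared dynamics, not
  about marginal significance. Consequently `run_pipeline` links all
  expressed lncRNAs by default and reports the differential-restricted
  panel alongside; on real data, where differential lncRNAs are the
  panel of interest, `link_lnc_panel = "differential"` restricts pairing
  accordingly.
* **Placement guarantees.** Genes sit on spaced slots; peak summits sit on
  a 1-kb grid with jitter, and coupled summits are re-placed within 50 kb
  of their lncRNA while keeping ≥ 600 bp from every other summit — so
  200-bp trimmed windows never merge and the count matrix stays keyed to
  stable peak identifiers.

What the generator does **not** emulate: read-level count noise,
tissue-specific biology, correlated replicate structure, genuine FDR
behaviour of dependent tests, or sequence composition of real loci
(`generate_sequences` draws i.i.d. bases). Passing tests therefore
demonstrate the correctness of the filtering, combination, pairing and
scoring logic under known truth — not the biological performance of the
thresholds on real data.

## Numerical and degenerate-input conventions

* Internal coordinates are 0-based half-open everywhere; GTF (1-based
  closed) is converted on read and on write, BED passes through.
* Fisher combination: chi-square tail from `pchisq`; the tests check it
  against the closed form `exp(-x/2)(1 + x/2)` to 1e-6 on 10,000 random
  pairs.
* BH adjustment: `stats::p.adjust(method = "BH")` per stratum; tests
  require exact equality with a brute-force step-up on random vectors.
* Pearson correlation must match the definitional formula to 1e-12;
  trajectories shorter than 3 points or with zero variance are rejected
  or excluded with a warning.
* All tie-breaks (nearest TSS, triad dedup, merged peak identifiers) are
  deterministic, and generators derive child seeds from the configuration
  seed, so identical configurations are byte-identical end to end —
  timestamps are confined to the run log.

## Sequence features

`find_smorfs` scans the three sense frames (the convention used when
building a translated search database from annotated transcripts); a
6-frame scan is intentionally not the default. An ORF is counted from the
A of ATG through the stop codon inclusive, so the 30-nt minimum means a
9-residue peptide; every ATG opens a candidate, including nested ones, and
all qualifying ORFs are reported (`longest_only` collapses to one per
sequence). GC content excludes ambiguity codes from numerator and
denominator and treats U as T. Group comparisons use the Mann–Whitney U
test for length/GC and the Kolmogorov–Smirnov test for distributions such
as externally computed minimum free energy, which the package consumes
but never computes (thermodynamic folding is out of scope).

## Known limitations

* The stratified BH substitute does not transfer information across
  tissues the way covariate-weighted FDR methods do; with few tests per
  stratum it is conservative.
* The background rate of local pairs passing r ≥ 0.5 is bounded below by
  the null distribution of the Pearson coefficient on 8 points,
  `P(r ≥ 0.5) ≈ 0.104`; shorter grids make this worse, and no generator
  setting can push it below that floor while background trajectories
  remain independent.
* Peak-to-gene assignment is nearest-TSS only; loop- or contact-based
  assignment is out of scope.
* The pipeline consumes effect tables; it does not fit the differential
  model, align reads or call peaks.

## Problem sizes used in the test suite

Unit tests run the generator at 15–80 genes and tens to hundreds of
peaks; the property checks use 500 lncRNAs × 2,000 peaks for pairing
against the all-pairs scan, 1,000 random sequences for the ORF oracle, 50
seeded runs for triad deduplication, and 20 seeds × ~10,000 local pairs
for planted-coupling recovery. These sizes were chosen so the whole suite
exercises every guarantee at meaningful scale while completing in a few
minutes.
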