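---
title: "Multi-batch TMT normalization and differential abundance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-batch TMT normalization and differential abundance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtbridge)
```

## The problem

Isobaric-label (TMT) proteomics quantifies up to eleven samples per mass-spectrometry
run ("batch" or "plex") through reporter-ion intensities. Designs with more samples
than channels must spread samples over several batches, and reporter intensities are
only comparable within a batch: channel loading differences and protein-specific
batch effects (different digestion, labeling and instrument response per run)
otherwise swamp the biology. The standard remedy is to label one or more *bridge*
channels in every batch with the same pooled mixture of all biological samples. The
bridges are identical material by construction, so any cross-batch difference in a
protein's bridge signal measures that protein's batch effect and can be divided out.

`tmtbridge` implements that pipeline for a two-batch, six-condition,
three-replicate layout (18 biological samples + 2 bridge channels per batch = 22
channels): the growth-condition comparison of an anaerobic organohalide-respiring
bacterium cultivated on combinations of electron donors (pyruvate, lactate, H2) and
acceptors (fumarate, the chlorinated phenoxyacetate ClOHPA), with pyruvate-only
fermentation as the sixth condition. Nothing in the code is specific to those labels
except defaults; arbitrary condition sets, batch counts and bridge counts are
supported.

## Pipeline

1. **Complete-case filter** (`complete_case_filter`). Only proteins with a positive
   intensity in every channel of every batch are analyzed. A stored intensity of 0 is
   treated as "not quantified": reporter intensities of zero are not usable
   measurements. Filtering happens *before* normalization because column sums and
   TMM are undefined on missing data; for proteins that are complete everywhere the
   resulting scale factors are the ones that matter downstream, and the retained set
   is by definition the same whichever order is used. The run report records the
   order.

2. **Sample Loading (SL) normalization** (`sample_loading_normalize`), per batch.
   Column *j* is multiplied by (mean of column sums)/(sum of column *j*), equalizing
   total reporter signal across a batch's channels under the assumption of equal
   protein load. After SL every column sum equals the grand mean of the original
   sums exactly (tested to 1e-12 relative).

3. **Internal Reference Scaling (IRS)** (`irs_normalize`), across batches. For
   protein *p* and batch *b*, the bridge mean `B(p,b)` is the arithmetic mean of the
   bridge channels (the natural summary of replicate measurements of the same
   mixture; a geometric option exists). The cross-batch reference is the geometric
   mean of the batch bridge means — symmetric in batch order, and the convention of
   the IRS method family — and every intensity of *p* in batch *b* is multiplied by
   `ref(p)/B(p,b)`. Afterwards each protein's bridge means agree across batches to
   machine precision (tested). Proteins with a zero bridge mean cannot be scaled and
   are dropped with a warning.

4. **Trimmed mean of M-values (TMM)** (`tmm_factors`), across all 22 channels of the
   merged matrix. We re-implement the published TMM algorithm on column-sum-scaled
   proportions: reference column = the one whose 75th-percentile proportion is
   closest to the mean of 75th percentiles; per column, M = log2 proportion ratio to
   the reference and A = average log2 proportion; rows in the top/bottom 30%
   quantiles of M or 5% quantiles of A (midpoint-tied ranks) are trimmed; the factor
   is 2^(precision-weighted mean of the surviving M), with inverse
   binomial-approximation variances as weights; factors are rescaled to geometric
   mean 1. The test suite checks the factors against an independently coded
   brute-force oracle (< 1e-9) and against `edgeR::calcNormFactors`. If fewer than
   two rows survive trimming the factor falls back to the untrimmed weighted mean
   with a warning. Note that with the precision weights the factors are exactly
   invariant under rescaling the whole matrix or under composition-preserving column
   changes, but only approximately invariant under rescaling a single column (the
   count-based weights shift); the exact forms are what the tests assert.

5. **log2 transform.** Complete-case values are strictly positive, so no pseudocount
   is needed. All downstream statistics are on the log2 scale.

6. **Moderated pairwise tests** (`all_pairwise_contrasts`). A one-way fixed-effects
   layout per protein: condition means are replicate averages, the residual variance
   s_g^2 is the pooled within-condition variance with d_g = n − k degrees of freedom
   (12 for 18 samples in 6 conditions). No batch covariate is fitted — IRS has
   already removed the protein-specific batch term; a sensitivity analysis with a
   batch factor can be run by fitting on the `skip_irs` output. Empirical-Bayes
   moderation estimates a scaled-inverse-chi-square prior (d0, s0^2) for the
   variances by moment matching on e_g = ln s_g^2 − ψ(d_g/2) + ln(d_g/2): the excess
   of var(e) over ψ'(d_g/2) is inverted through the (strictly decreasing) trigamma
   function by a bounded Newton iteration; a non-positive excess gives the
   degenerate limit d0 = ∞, s0^2 = exp(mean(e)). The posterior variance
   (d0·s0^2 + d_g·s_g^2)/(d0 + d_g) feeds a moderated t with d0 + d_g degrees of
   freedom, two-sided p-values, and all C(6,2) = 15 unordered contrasts are tested
   once (antisymmetry is then exact by construction). Benjamini-Hochberg adjustment
   (`bh_adjust`, a validated wrapper over `stats::p.adjust`) is applied within each
   contrast separately, matching the "FDR < 0.05 in at least one pairwise
   comparison" selection idiom. Degenerate zero-variance rows (possible on synthetic
   noise-free data) get t = ±∞ (p = 0) for a non-zero difference and t = 0 (p = 1)
   otherwise. No variance trend ("limma-trend") or robust estimation is fitted in
   this version; the plain moderation was chosen as the simplest model consistent
   with the pipeline's claims.

7. **Set logic** (`select_proteins`, `any_vs_all_partition`, `quadrant_select`,
   `strict_group_select`). All rules use strict inequalities: logFC > 1 (two-fold)
   and FDR < 0.05 by default, boundary values excluded. The union/intersection
   partition around one focal condition mirrors Venn-style "up against any" /
   "up against all" summaries; the quadrant selector classifies joint direction in
   two parallel contrasts (both-up / both-down / mixed); the strict group selector
   requires the rule in every A×B cross-contrast. Contrast identifiers are oriented
   automatically, so `"H2/Fu_vs_La/Fu"` works even though the table stores the pair
   in condition order. Fold-change display (`fold_change_format`) renders 2^|logFC|
   to the nearest integer at ratios ≥ 2 and one decimal below, always with a decimal
   point, flagging down-regulation.

8. **Structure** (`zscore_rows`, `hcluster_cut`, `pca_samples`, `heatmap_export`).
   Z-scores are computed per protein across the 18 biological samples (bridges
   excluded), n−1 denominator; constant rows become zero with a warning. Clustering
   is agglomerative on Euclidean row distances; the linkage is a required choice the
   upstream description leaves open — complete linkage is the default (the common
   default of the heatmap tooling family), switchable to average/Ward. Rows are
   sorted by id before clustering so the partition is row-order invariant, and
   cluster labels are renumbered by decreasing size. The number of clusters k is a
   user parameter (`run_config(k = 9)` by default, matching a nine-cluster heatmap
   convention); nothing in the package chooses k automatically. Clustering operates
   on the regulated subset: proteins passing the |logFC| > 1 ∧ FDR < 0.05 rule in at
   least one contrast. PCA treats samples as observations and proteins as centered
   variables; explained-variance fractions sum to 1, and bridges may be included to
   check that the pooled mixtures sit centrally.

## The synthetic generator

`simulate_dataset(sim_config())` draws, on the log2 scale,

```
log2 I(p, s in batch b, channel j) = baseline_p + effect_{p, cond(s)}
                                     + batch_{p,b} + loading_j + noise_{p,j}
```

with baseline ~ N(20, 2), protein-specific batch effect for batch 2 ~ N(0, 0.5)
(identical for every channel within the batch — exactly the structure IRS removes),
channel loading ~ N(0, 0.3), and multiplicative log-normal noise N(0, 0.25) per
cell. Bridge channels are mixed on the *linear* scale (a pooled sample mixes mass,
not logs) from the noise-free true signals of all 18 samples, then acquire the
measuring batch's batch effect plus their own loading and noise. Dropout is
independent per (protein, channel) at rate 0.05, so a 22-channel complete case
survives with probability 0.95^22 ≈ 0.32. Effects follow six archetypes —
constitutive, Py-only-up, H2-up, lactate-up, ClOHPA-up, Py-only-down — at ±1.5 log2
units, 10% of proteins regulated in total, giving every selector a non-empty ground
truth. The noise magnitudes are package choices (typical protein-level TMT
coefficients of variation are in the 15–25% range; the emulated study reports none)
and are deliberately fixed: they are the study conditions under which the recovery
claims are tested, not tuning knobs.

Batch allocation is not stated in the emulated design, so the generator uses a
balanced interleave (replicate r of condition c goes to batch 1 + ((c + r) mod 2)):
every condition appears in both batches, the standard randomized-block practice
when a design must span plexes.

What the generator does **not** emulate: peptide-level aggregation, ratio
compression from co-isolation interference, intensity-dependent (MNAR)
missingness, and correlated noise between channels. Recovery results on this
generator therefore validate the arithmetic and the statistical engine — they do
not certify performance on real reporter data, where interference and structured
missingness are the dominant complications.

## What bridge correction can and cannot fix

IRS removes the protein-specific batch term exactly, but its correction is itself a
measurement: with two bridge channels per batch and per-channel log2 noise σ, the
log bridge mean carries noise ≈ σ/√2 per batch, so a contrast between conditions
with unequal batch composition inherits extra error on top of the replicate-mean
noise. With the default σ = 0.25 and triplicates, the replicate-mean term alone has
sd 0.25·√(2/3) ≈ 0.20. Under the balanced allocation the batch-composition
imbalance between any two conditions is at most one replicate, which both (a) caps
the batch-effect leakage when IRS is disabled at one third of the per-protein batch
effect and (b) caps the bridge-noise leakage when IRS is enabled at one third of
the bridge-mean difference. The two regimes therefore differ only modestly in
median logFC error at these settings — the acceptance script reports both, plus
their ratio (`irs_disabled_error_ratio`) — whereas the QC consequence of skipping
IRS is unambiguous: the per-protein bridge means disagree across batches by the
full batch effect (the `bridge_qc` flag in the run report). IRS earns its keep
decisively in confounded allocations (whole conditions per batch), at the price of
funnelling bridge measurement noise into every cross-batch contrast; with designs
like these, more bridge channels per batch directly buy logFC accuracy.

## Numerical choices

* TSV numbers are written with the C `%.17g` format, so write→read round trips are
  bit-exact and repeated runs produce byte-identical artifacts.
* TMM trims use midpoint-tied ranks (`rank`, ties = average), matching the canonical
  implementation; reference-column ties resolve to the first column.
* The trigamma inversion starts at 0.5 + 1/y and Newton-iterates to 1e-10 relative;
  it is exact on round trips over five orders of magnitude (tested).
* Cluster-label ties (equal sizes) break on the smallest member id; dendrogram leaf
  order is the export order.
* Degenerate inputs fail loudly and early: zero column sums, batches without
  bridges, duplicate accessions, conditions with fewer than two replicates, empty
  complete-case sets.

## Problem sizes used in validation

The test and acceptance runs use the generator's default scale — 2,000 proteins per
dataset (≈ 650 complete cases after dropout), five datasets pooled for the recovery
metrics, fifty random 200×6 matrices for the TMM oracle, and 5,000 simulated
variances for prior recovery — sizes at which the binomial/quantile bounds used in
the assertions are tight while a full run stays interactive.

## Known limitations

* SL factors are computed at the protein level; descriptions of the method at the
  spectrum level are equivalent in form but not in value if peptide-spectrum matches
  are weighted differently.
* Only complete cases are analyzed; there is no imputation path.
* BH control is per contrast; no across-contrast multiplicity correction is
  attempted.
* The moderated model has no intensity-variance trend and no robust option.
* Venn-style rendering is left to the caller; the package emits the membership
  tables.
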