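---
title: "Methods: integrating chromatin accessibility with gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating chromatin accessibility with gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspeak)
```

# The analysis

`crosspeak` implements the statistical core of a paired ATAC-seq/RNA-seq
study of a six-condition cell-culture design (an immediately collected
baseline, a 24 h culture point, and day-1/day-5 points in either plain
culture medium, CM, or a vitreous-supplemented differentiation medium,
DM; three RNA replicates and two ATAC replicates per condition).  The
pipeline answers three questions:

1. **Which features change, and in what archetypal patterns?**
   Counts are normalized by median-of-ratios size factors, features are
   tested between all fifteen condition pairs, filtered at
   |log2 fold change| ≥ 1.5 and Benjamini–Hochberg adjusted p ≤ 0.05
   (both boundaries inclusive), the per-comparison survivors are pooled
   into a non-redundant union, and the union is clustered into k = 6
   archetypes by Hartigan–Wong K-means on row-z-scored normalized counts.

2. **Do accessibility archetypes align with expression archetypes?**
   Each peak is annotated to its nearest TSS, mapped to that gene, and a
   k × k cross-table of joint (RNA cluster, ATAC cluster) gene counts is
   tested globally by a Pearson chi-squared test and per cell by a
   fixed-margin permutation test: one label vector is uniformly permuted
   100,000 times and a cell is *associated* when fewer than 5% of the
   permuted counts reach its observed count.

3. **Does promoter accessibility track expression?**  A pooled Pearson
   correlation across all (gene, condition) pairs; per-gene correlations
   binned into strong/moderate/none categories; a 3 × 3
   direction-concordance table between the modalities for a CM-vs-DM
   comparison, with a two-sided Fisher exact test for curated direction
   sets; TSS metaprofiles of accessibility by expression quintile; and a
   binned PWM motif enrichment over differential-accessibility fold
   changes.

Every stage is driven either by real inputs (GTF gene models,
BED/narrowPeak peaks, TSV count matrices, JASPAR motifs, or externally
computed differential tables via `read_diff_table()`) or by the
package's synthetic-data generator, which plants known cluster labels,
cluster associations, and expression–accessibility correlations so each
stage can be tested against ground truth.

# Statistical machinery and its assumptions

## Normalization and the differential stand-in

Size factors follow the median-of-ratios definition: for sample $j$,
$s_j = \operatorname{median}_{i \in R}\, c_{ij} / (\prod_k c_{ik})^{1/n}$
over the reference set $R$ of features with strictly positive counts in
every sample.  This assumes most features are not changing; it is the
estimator the upstream count-based differential frameworks use, and the
implementation is cross-checked against one of them in the test suite.

The package deliberately does **not** re-implement a negative-binomial
GLM.  Its `differential_standin()` uses the pseudo-counted ratio of
normalized group means, $\log_2\!\big((\bar c_B + 0.5)/(\bar c_A +
0.5)\big)$, with a Welch t-test on $\log_2(\text{normalized}+1)$ and BH
adjustment within each comparison.  With two or three replicates the
Welch–Satterthwaite approximation is only approximate, so null p-values
are close to, but not perfectly, uniform; the calibration test checks
uniformity by a Kolmogorov–Smirnov test at α = 0.01 on 2,000 null
features, which this approximation passes but without a wide margin.
For real data, externally computed differential tables should be
injected via `read_diff_table()`; the stand-in exists to exercise the
downstream integration logic on synthetic data.

The fold-change filter is applied to |LFC|: the study design is
symmetric in the two conditions of each comparison and both directions
are reported downstream, so a one-sided reading of the threshold would
be inconsistent with the analyses that consume it.

## Clustering

`kmeans_features()` z-scores each feature row before clustering so that
archetype *shape*, not magnitude, drives the partition — this matches
the z-score heatmaps such analyses display, although scaling is a
package choice rather than something the upstream workflow prescribes.
Hartigan–Wong with `n_start = 25` random initializations is used; a run
that converges with an empty cluster is re-initialized.  Labels are
arbitrary up to permutation, so all recovery tests compare clusterings
by adjusted Rand index, never by raw label identity.  No model-selection
procedure for k is provided; k = 6 is the default for both modalities.

## Genomic annotation

Each peak is represented by a single anchor — the summit when present,
else the interval midpoint — which guarantees exactly one category per
peak.  Eleven categories are assigned by a precedence ladder: promoter
bins at ≤ 1 kb, 1–2 kb and 2–3 kb from the nearest TSS (distance signed
in gene orientation, negative upstream; boundaries inclusive), then
5' UTR, 3' UTR, first exon, other exon, first intron, other intron, a
downstream window past the gene 3' end, then distal intergenic.  The
ladder mirrors the default priority of the widely used annotation tools
in this field.  Two open choices are resolved explicitly:

* **TSS level.** The TSS is defined at gene level on the union
  transcript span (transcript-level TSS selection is not modelled).
* **Downstream window.** 300 kb by default, following the category
  description this scheme comes from; several annotators default to
  300 bp, so the window is a parameter (`downstream_window`).

All internal interval arithmetic is 1-based inclusive — the native
convention of the IRanges/GenomicRanges stack used for the overlap
queries — with BED/narrowPeak's 0-based half-open coordinates converted
once at the parse boundary.

## Cross-table association

Under fixed cluster sizes, permuting one label vector uniformly is
distributionally identical to permuting both (only the relative
alignment of the two labelings matters); the implementation permutes
one for speed.  This choice has a sharp consequence used throughout the
tests: each cell count is then exactly hypergeometric, so the Monte
Carlo empirical p has a closed-form oracle.  The per-cell criterion —
empirical p < 0.05 with p defined as the fraction of permuted counts
**greater than or equal to** the observed count — is applied without
multiple-testing correction across the 36 cells, matching the stated
5% per-cell rule.  Because counts are discrete and the rule includes
equality, the realized null flag rate is mildly conservative (about
4.4% rather than 5% at the calibration test's problem size); the
calibration test bounds the rate within three binomial standard
deviations of 5%.

A gene with several mapped peaks takes the ATAC cluster of its nearest
peak by default (`multi_peak = "majority"` is available); the upstream
description is silent on this.

## Correlation

RNA has three replicates, ATAC two, so samples cannot be paired
one-to-one; both modalities are collapsed to per-condition replicate
means and paired by condition.  Correlations are computed on
`log2(x + 1)` of normalized counts by default.  The log scale matters:
normalized counts are approximately log-normal across genes and
conditions, and the pooled Pearson correlation of log-normal variables
is substantially attenuated relative to the correlation of their logs
(at this generator's amplitudes, a planted log-scale correlation of 0.6
yields a raw-scale pooled r of roughly 0.4).  Parameter recovery of the
planted correlation is therefore only faithful on the log scale;
`log2 = FALSE` restores the raw behaviour.

Per-gene correlation categories default to strong |r| ≥ 0.9, moderate
0.5 ≤ |r| < 0.9, none otherwise.  These cutoffs are configuration, not
an inference: with only six condition-level points a per-gene r carries
a Fisher-z standard error of about 0.58, so neighbouring categories
blur freely.  The recovery test accordingly checks the sign class
(positive / none / negative) rather than the five-way label.

## TSS quintile profiles

Genes are ranked within each condition by mean normalized expression
(replicates collapsed by mean; ties broken by a stable sort on gene
id), split into five equal-size bins with any remainder pushed to the
lowest-expression bins, and the TSS-centred coverage is averaged per
bin.  The coverage window is ±2 kb in 10 bp bins — 401 bins, odd on
purpose so one bin sits exactly on the TSS and a noiseless profile has
a unique maximum there.  Profiles are oriented so upstream is left.

## Motif enrichment

`scan_pwm()` scores every window on both strands with log2-odds against
the background, after adding a 0.5 pseudocount per PFM cell at parse
time (so no log-odds is infinite); `N` bases contribute zero.  A window
is a hit at ≥ 80% of the motif's maximum attainable score by default.
Regions are binned by differential-accessibility LFC into an odd number
of bins: a centre bin holding the non-differential zone |LFC| < 1.5 and
equal-count bins per side (the most extreme fold changes outermost).
Per (motif, bin), enrichment is a one-sided hypergeometric test of the
bin's hit count against all other bins, significant at p < 5 × 10⁻⁵.
This bin-vs-rest hypergeometric is a deliberate simplification of the
binned motif machinery it emulates; it is validated by null calibration
(unplanted motifs must reach significance in < 1% of (motif, bin)
pairs) rather than by tool equivalence.  GC content per bin is not
corrected for.

# The synthetic-data generator

`sim_config()` defaults *are* the emulated study conditions: 2,000
genes and 6,000 peaks on one 20 Mb chromosome, six conditions with 3
RNA / 2 ATAC replicates, six archetype clusters per modality with
shapes mimicking the published cluster descriptions, negative-binomial
(Gamma–Poisson) counts around `depth × 2^(baseline + 2 × archetype)`
with a single shared dispersion of 0.05, log-normal depth factors
(sd(log) = 0.2), a planted one-to-one cluster association (odds 5 on
the diagonal), and a planted expression–promoter-accessibility
correlation of 0.6.

Design points worth knowing:

* **Association is planted on labels, not counts.**  Gene (RNA, ATAC)
  cluster pairs are drawn jointly with probability proportional to the
  odds matrix, so cross-table analyses have exact ground truth and the
  all-ones odds matrix is an exact independence null (cell counts
  hypergeometric given margins).
* **Correlation is planted through a shared latent profile.**  Each
  gene's promoter peak mixes the gene's standardized condition signal
  with an independent standardized profile at weights ρ and
  √(1 − ρ²), and peak baselines couple to gene baselines the same way,
  so the log-scale correlation between expression and promoter
  accessibility is ρ by construction.  Distal distractor peaks carry
  pure ATAC archetypes.  Residual count noise and the `log2(x+1)`
  nonlinearity attenuate the recovered pooled r slightly (≈ 0.55
  recovered for ρ = 0.6), which is inside the ±0.1 recovery band the
  tests require.
* **One promoter peak per gene** is placed within 1 kb of the TSS;
  distal peaks are rejected within 1.5 kb of any TSS, so promoter-bin
  annotation of the planted peaks is unambiguous.
* **Dispersion 0 is exactly noiseless** (counts are rounded means, not
  Poisson draws), giving clean closed-form fixtures for limit tests.

What the generator does *not* emulate: per-feature dispersion, batch
effects, fragment-length/insertion-site structure, GC or mappability
bias, correlated peaks beyond the single promoter peak, and read-level
data.  Tests passing on this generator therefore validate the
*pipeline logic* — normalization arithmetic, filtering, label handling,
the permutation and hypergeometric machinery, annotation geometry,
scanner correctness — not robustness to the full messiness of real
libraries.

# Numerical choices and degenerate inputs

* Thresholds are boundary-inclusive (`>=`, `<=`) wherever the
  filtering rules state them that way.
* Fold ratios across days are rounded to one decimal; a zero
  denominator reports `NA` (undefined), never infinity.
* A gene constant across samples cannot be z-scored and is dropped
  from clustering with a warning; a zero-variance correlation vector
  yields `r = NA`, category `none`.
* Nearest-TSS ties are broken by lexicographically smaller gene id;
  quintile ties by a stable sort on gene id; equal-count LFC bins
  differ by at most one region, extras outermost (left side) to keep
  side symmetry.
* BH adjustment delegates to the standard step-up implementation;
  p-values outside [0, 1] are rejected, not clamped.
* The empty annotation (0 genes), the empty count matrix (0 features)
  and sequences shorter than a motif are all valid degenerate inputs
  with defined behaviour.

# Problem sizes used by the test and acceptance runs

Unit tests run on 50–600 gene simulations.  The acceptance suite uses
the published 6 × 6 cross-table (N = 7,193 genes) with the full 100,000
permutations; 1,000-gene simulations (three seeds) for correlation
recovery; 600-gene simulations for ARI recovery; fifty 2,000-gene
simulations per odds setting for association flagging; fifty 300-region
simulations for motif calibration; and a 2,000-gene null for p-value
calibration.  These sizes were chosen so the whole suite completes in a
few minutes on one CPU while keeping every binomial tolerance band
meaningful.

# Known limitations

* The stand-in differential test is not a substitute for a proper
  count model on real data; inject real differential tables instead.
* Gene-level TSS only; alternative promoters are invisible.
* The motif stage does not correct for GC or sequence composition.
* The global correlation depends on the peak set fed into
  `gene_level_atac()`: averaging distal peaks into a gene dilutes the
  promoter signal (the tests restrict to promoter-bin peaks when
  recovering the planted correlation).
* `empirical_p` can be exactly 0 with a finite permutation count; the
  association rule only needs the 5% comparison, but users quoting
  these p-values should report them as `< 1/n_perm`.
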