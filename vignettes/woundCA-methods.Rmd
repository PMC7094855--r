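---
title: "Screening wound-age markers with an arctangent-degree correspondence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening wound-age markers with an arctangent-degree correspondence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundCA)
```

## The problem

Forensic wound-age estimation asks how long before death (or sampling) a
wound was inflicted. Incised skeletal muscle mounts a stereotyped
transcriptional response — inflammatory chemokines and cytokines surge
within hours, muscle-structural genes fall — so the *ordering* of a gene's
fold changes across 6, 12 and 24 h post-injury carries timing information.
`woundCA` implements a screening pipeline for microarray time courses of
the standard design (4 time points × 4 replicate animals = 16 arrays):
flag-based quality control and percentile normalization, ANOVA/Tukey
differential calling, an arctangent-degree transform of fold changes
followed by correspondence analysis (CA), geometric dissection of the
biplot into six fold-change-ordering areas, distance-based gene sets, and
Fisher/PAGE gene-set enrichment.

## Preprocessing and quality control

Scanner-exported signals are normalized in four steps:

1. signals below background (negative after background subtraction) are
   set to 1, read as "not expressed";
2. the four replicates at each time are collapsed to their geometric mean;
3. representative values are taken to log2;
4. each time point's 75th percentile is subtracted from every gene,
   assuming most genes do not fluctuate.

Fold changes `FC6/FC12/FC24` are ratios of the non-log normalized values
(`2^` of step 4) at each time to the control's. Percentiles use linear
interpolation between order statistics (`stats::quantile` type 7), the most
common convention; this choice only matters for small gene counts.

Each feature carries one flag per array, `Dt` (Detected), `NDt` (Not
Detected) or `Cm` (Compromised). A feature is `Dt` only when all 16 arrays
say so; a single `Cm` anywhere excludes the feature, and `Cm` is given
precedence over `NDt` when both occur — the conservative reading, since
`Cm` marks compromised measurements. `Dt` and `NDt` features are retained.

Step 2 collapses replicates, yet the significance tests need them. The
package therefore keeps **two tracks**: the representative track (steps
1–4 verbatim) feeding fold changes and CA, and a per-array track (clip,
log2, per-array 75th-percentile shift) feeding ANOVA and Tukey. Which
per-sample quantity the original analysis fed its ANOVA is not derivable
from the published description; the per-array track is this package's
explicit design choice, and the multiplicative-rescaling invariance of both
tracks is covered by tests.

## Differential calling and the 27-pattern taxonomy

Per gene, a one-way fixed-effects ANOVA across the four time groups is
screened at BH-adjusted p < 0.05 (one BH family: all genes). Screened genes
get Tukey's HSD (all six pairwise contrasts define the studentized-range
null; only the three control-versus-time contrasts are consumed),
BH-corrected per contrast across the screened genes. A call of `U`/`D`
requires adjusted contrast p < 0.05 with the matching sign; everything else
is `-`. The triple of calls at 6/12/24 h is the gene's pattern code — 27
possible codes. The BH family structure (per test type, per contrast) is a
documented choice; the published description does not define families.

ANOVA F statistics and Tukey p values are computed row-wise by the
sum-of-squares and studentized-range formulas (via `pf`/`ptukey`) so that
10⁴–10⁵ genes are tested in seconds; tests verify exact agreement with
`aov()`/`TukeyHSD()` per gene. Genes with zero variance everywhere have an
undefined F and are reported as no-calls with a warning.

Threshold gene sets collect genes Tukey-significant at a time point with
`FC > 3` (or 5) for up, `FC < 1/3` (or 1/5) for down — strict
inequalities, reciprocal thresholds, so the 3-fold set always contains the
5-fold set.

## The arctangent-degree transform and CA

Each fold change is mapped to a degree value

$$d(\mathrm{FC}) = \frac{180}{\pi}\arctan\!\left(\frac{1}{\mathrm{FC}}\right) \in (0^\circ, 90^\circ),$$

so FC = 1 ↦ 45°, large fold changes approach 0°, and strong
downregulation approaches 90°, with the complement identity
`d(FC) + d(1/FC) = 90`. Unlike a log transform the degree scale is bounded,
damping the influence of extreme ratios (FC > 10 or < 0.1). The genes × 3
degree matrix (6, 12, 24 h) is then analysed by classical simple CA:
correspondence matrix `P`, row/column masses, SVD of the standardized
residuals, principal coordinates for rows *and* columns (symmetric map, so
gene-to-score Euclidean distances are meaningful). A 3-column table has
exactly two non-trivial dimensions, so the first two factors always carry
100% of the inertia; the package verifies internally that the transition
formulas hold (`transition_check()`), and the test suite checks the
chi-square-distance identity against a brute-force oracle and cross-checks
coordinates against an independent CA implementation.

SVD signs are arbitrary, so axes are oriented by convention: the 24 h
column score is non-negative on Factor 1 and the 6 h score non-positive on
Factor 2. All distances and area assignments are invariant under joint sign
flips.

## Biplot geometry: areas, boundary lines, point P

A gene's position in the biplot is a linear function of its degree
*profile* (its degree triple divided by its sum). The locus where two
degrees are equal — equivalently where two fold changes are equal — is
therefore an exact straight line in the plot, and the six strict orderings
of (FC6, FC12, FC24) occupy six wedge-shaped areas labelled A–F. Exact
ties get a tie marker rather than an arbitrary label.

The three boundary lines are estimated from data: among the `q` genes whose
two boundary fold changes have log-ratio closest to 0 (default `q = 100`,
mirroring a top-100 candidate pool), the pair with maximal biplot
separation anchors the line — a reproducible stand-in for manually picking
genes "at the ends" of each area. Point P, the approximate common
intersection, is the least-squares point minimizing summed squared
perpendicular distances to the three lines; it coincides with the pairwise
intersection when the lines are concurrent. Because genes with the
smallest fold change at 12 h and the largest at 6 h surround the origin,
the boundaries generally do not pass through (0, 0).

Two kinds of distance-based gene sets are built by ranking Euclidean
distances in the plot: distance 1 to each time-series column score, and
distance 2 to each of the top-5 query genes (most extreme FC per time point
and direction, ties broken by gene id). Top-k sets are ranking prefixes,
so top-100 ⊂ top-300 ⊂ top-1000 by construction.

## Enrichment

Gene sets are tested against a GMT catalog by the one-sided Fisher exact
(hypergeometric upper-tail) test; pathway-category terms are additionally
tested with PAGE, `Z = (Sm − μ)·√m / δ`, where `Sm` is the term's mean
score, `μ`/`δ` the mean and sd over all universe genes, and the score is
the log2 fold change at the set's defining time point (the canonical PAGE
input; the published description says only "average fluctuation"). PAGE p
values are two-sided — the published account does not say, and two-sided is
the safer default since pathways may move either way. The universe is all
QC-retained genes; BH families are per gene set per catalog category.

## The synthetic-data generator

`generate_study()` emulates the study design so every stage is testable
without downloads: per-gene baselines `N(8, 2)` on log2 (a bright, widely
spread microarray intensity distribution), planted per-time shifts of
±`effect_log2fc` (default 3, i.e. 8-fold — comfortably beyond the 3- and
5-fold thresholds) according to a sampled 27-category pattern mix (default
70% unchanged), additive Gaussian replicate noise on log2 (default sd
0.25, a moderate microarray replicate CV; the source study reports no
replicate variance, so this is an assumption, not an estimate), and
independent per-feature per-array flags (defaults: 5% NDt, 1% Cm). The
annotation catalog plants `n_enriched_terms` terms containing an exact
fraction of up-pattern genes by construction. One seed drives everything;
identical configuration is bitwise-reproducible.

`generate_geometry_study()` builds fold-change tables for geometry
recovery: independent lognormal fold changes (log2 sd 2, spreading genes
over all six areas) plus planted boundary tracers whose two boundary fold
changes are exactly equal across the full magnitude range — the
construction under which the anchor rule recovers the boundary lines
exactly. `generate_worked_fixture()` is a 16-gene deterministic fixture
whose geometric means, percentiles, fold changes and areas are
hand-computable (constant filler genes pin all column percentiles to one
value so shifts cancel in the fold changes).

What the generator does *not* emulate: probe-sequence effects, spatial
artefacts, correlated flags, heavy-tailed noise, and the mild
intensity-dependence of microarray variance. Passing tests therefore
demonstrate correctness of the computations under a clean generative
model, not robustness to real-array artefacts.

## Numerical choices and scales

* Percentile: type-7 linear interpolation; degenerate all-constant columns
  shift to zero.
* CA: total inertia below 1e-20 is treated as exactly degenerate (all
  points at the origin); the trivial CA dimension is discarded by
  construction rather than thresholding.
* Ties: everywhere broken lexicographically by gene id so runs are
  reproducible.
* Problem sizes: the test suite runs studies of 10²–10⁴ genes — 10⁴
  matches the scale at which calibration statements (type-I error, KS
  calibration, ≥ 99% boundary-side agreement) are sharp, while keeping a
  full run in seconds.

## Limitations

* The pipeline assumes the balanced 4 × 4 design; unbalanced Tukey
  (Tukey–Kramer) is not implemented.
* Boundary-line recovery is exact only when near-boundary genes exist;
  with sparse coverage the anchor rule degrades gracefully but the
  fitted line is then only approximate.
* GO-hierarchy propagation and topology-aware pathway statistics are out
  of scope; catalogs are flat GMT lists.
* Re-analysis of the deposited accession requires a download and an
  adapter from scanner flag columns to Dt/NDt/Cm; it is not part of the
  test surface.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  simulate = list(n_genes = 2000, n_terms = 30, term_size = 40,
                  n_enriched_terms = 5),
  out_dir = "run1", seed = 1)
res <- run_pipeline(cfg)
print(res$ca)
print(res$geometry)
head(res$enrichment$summary)
```
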