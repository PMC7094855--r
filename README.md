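# woundCA

Screening of wound-age marker genes from microarray time courses of
incised skeletal muscle.

Wounded muscle mounts a fast, ordered transcriptional response: chemokines
and cytokines surge within hours of an incision, structural muscle genes
fall, and the *ordering* of a gene's fold changes at 6, 12 and 24 h
post-injury versus uninjured control carries information about the age of
the wound — a question of direct forensic interest. `woundCA` implements
the full screening pipeline for the standard 4-time-point × 4-replicate
(16-array) design, for researchers analysing such time courses or
evaluating the method on simulated data.

## The method

1. **QC + normalization.** Features are kept only if no array flags them
   Compromised (`Cm`); a feature is Detected (`Dt`) only when all 16
   arrays agree, else Not Detected (`NDt`); `Dt`/`NDt` features are
   retained. Signals below background are clipped to 1, replicates
   collapsed by geometric mean, log2-transformed, and each time point is
   centred on its 75th percentile. Fold changes FC6/FC12/FC24 are
   non-log ratios of normalized signal at each time to control.
2. **Differential patterns.** Per-gene one-way ANOVA (BH-screened at
   0.05), then Tukey HSD control-versus-time contrasts (BH per contrast);
   each gene gets a pattern code over {U, D, −}³ — 27 categories — plus
   3-fold / 5-fold threshold gene sets (strict `FC > 3`, `FC < 1/3`, …).
3. **Arctangent-degree CA.** Each FC is mapped to
   `d(FC) = (180/π)·arctan(1/FC) ∈ (0°, 90°)` (so FC = 1 ↦ 45°, strong
   upregulation → 0°, strong downregulation → 90°), and the genes × 3
   degree matrix is decomposed by classical correspondence analysis; for
   3 columns the two leading factors carry 100% of the inertia, giving
   a faithful 2-D biplot of genes and time-series scores.
4. **Biplot geometry.** The six strict orderings of (FC6, FC12, FC24)
   occupy six areas A–F of the plot; the three between-area boundaries
   are straight lines fitted from anchor genes whose boundary FC pair is
   closest to equal, and point P is their least-squares common point.
   Distance-based gene sets collect the top-k genes nearest each
   time-series score ("distance 1") or each top-5 query gene
   ("distance 2").
5. **Enrichment.** Gene sets are tested against GMT catalogs with the
   one-sided Fisher exact test and — for pathway terms — the PAGE
   statistic `Z = (Sm − μ)·√m / δ`, BH-corrected per set and category.

A seeded synthetic-study generator with planted patterns, flags and
enriched terms makes the whole pipeline testable end to end.

## A worked example

```r
library(woundCA)
cfg <- pipeline_config(
  simulate = list(n_genes = 2000, n_terms = 30, term_size = 40,
                  n_enriched_terms = 5),
  out_dir = "run1", seed = 1)
res <- run_pipeline(cfg)
print(res$ca)
#> Correspondence analysis: 1696 rows x 3 columns
#>  Factor Eigenvalue Contribution Cumulative
#>       1    0.01896       0.5564     0.5564
#>       2    0.01512       0.4436     1.0000
print(res$geometry)
#> geometry_model: 1696 genes
#> areas: A=494  B=357  C=212  D=145  E=166  F=322
#> line 1: y = -0.1592 x +0.0084  (anchors gene_00559, gene_00702)
#> line 2: y = 1.2287 x -0.0123  (anchors gene_00570, gene_01544)
#> line 3: y = -2.5199 x +0.0377  (anchors gene_00405, gene_01994)
#> point P: (0.0136, 0.0055)
```

Of the 2,000 simulated features, 1,696 survive flag QC (a single `Cm`
call excludes a feature). The CA of their degree matrix is exactly
two-dimensional — the cumulative contribution reaches 100% at Factor 2 —
and the biplot splits into the six fold-change-ordering areas around
point P. The planted enriched terms are recovered in the upregulated
threshold sets:

```r
subset(res$enrichment$summary, category == "planted" & grepl("up", set))
#>        set category n_significant
#>    t6_up_3  planted             5
#>    t6_up_5  planted             5
#>   t12_up_3  planted             5
#>   ...
```

All five planted terms are significant in every upregulated set; the
downregulated sets recover none, as planted. Every stage also lands in
`run1/` as TSV tables (normalized signals, fold changes, per-gene calls
and pattern counts, CA scores and eigenvalues, per-gene geometry, boundary
lines, query genes, distance sets, enrichment results) plus a JSON run
manifest recording the seed and filter counts.

Single functions are usable on their own, e.g.

```r
degree_transform(c(0.2, 1, 5))
#> [1] 78.69007 45.00000 11.30993
assign_area(3163.200, 2260.396, 227.743)   # FC24 < FC12 < FC6
#> [1] "D"
```

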