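# sigshift

Cell-population signature genes and directional enrichment for bulk
expression studies.

## The problem

Bulk transcriptomes of solid tissue confound cell-intrinsic regulation
with changes in cellular composition: an "aging signature" in liver may
simply be immune cells moving in, and a genotype difference may be fat
accumulating or receding.  sigshift reads composition shifts out of
ordinary gene-by-sample expression matrices in three steps:

1. **Moderated differential expression.**  Gene-wise two-group (and
   genotype x age interaction) fits on log2 expression with
   empirical-Bayes variance shrinkage: variances are squeezed toward a
   prior `s0²` with `d0` prior degrees of freedom estimated by the
   closed-form moments method on log variances, and the moderated
   statistic `t_g = log2FC_g / (s̃_g · c)` gains `d0` degrees of
   freedom.  Detection-based gene filtering (above-background in at
   least one third of the comparison's samples) and DEG calling at
   FDR < 0.10 with FC > 1.50 or FC < 0.67 are built in.

2. **Two-stage signature derivation.**  From a labeled reference
   compendium of sorted cell populations, each population's signature is
   derived from its one-vs-rest contrast: keep genes with FC > 1, take
   the 150 with lowest p, keep the 100 with highest FC.  A
   decreased-expression variant covers treatment-response signatures.

3. **Directional enrichment.**  For a signature S and a fold-change
   vector, sigshift reports the Wilcoxon rank-sum bias of signature vs
   background log2 fold changes as a signed log10 p
   (`-log10(p) · sign(median_S − median_bg)`), the up/down direction
   counts with a Fisher exact test and its hypergeometric null band, and
   the cumulative-overlap curve whose trapezoid AUC equals the
   Wilcoxon–Mann–Whitney `U/(n1·n2)`.

A qPCR module (2^−ΔΔCt relative expression with protected Fisher's-LSD
compact letter displays) and synthetic-data generators with recorded
ground truth round out the pipeline.  Everything is tidyverse-shaped:
data frames in, tibbles out, `tidy()`/`glance()` on fitted objects,
`autoplot()` on result types.

## Worked example

Simulate a study in which a B-cell-like population infiltrates old
knockout livers only, derive signatures from a companion compendium, and
ask which population explains the old-KO vs old-WT contrast:

```r
library(sigshift)

sim <- simulate_preset("infiltration", seed = 1)
der <- derive_all(sim$compendium$expression, sim$compendium$samples)

de <- fit_moderated(sim$study$expression, sim$study$samples,
                    contrast = c("old-KO", "old-WT"),
                    detection = sim$study$detection)
glance(de)
#> # A tibble: 1 × 7
#>   contrast         n_genes n_included   n_a   n_b prior_df prior_var
#>   <chr>              <int>      <int> <int> <int>    <dbl>     <dbl>
#> 1 old-KO_vs_old-WT    2000       1821     8     6     3.07    0.0396

rank_signatures(as_fc_vector(de), der$collection) |>
  dplyr::select(signature, n_used, mean_fc, signed_log10p, n_up, direction_p, auc)
#> # A tibble: 5 × 7
#>   signature n_used mean_fc signed_log10p  n_up direction_p   auc
#>   <chr>      <int>   <dbl>         <dbl> <int>       <dbl> <dbl>
#> 1 pop02         91   3.48         55.4      90    1.12e-22 0.990
#> 2 pop03         92   1.03          0.376    58    1.61e- 1 0.525
#> 3 pop05         92   1.00         -0.720    50    8.30e- 1 0.460
#> 4 pop04         85   1.00         -1.23     34    3.57e- 3 0.439
#> 5 pop01         89   0.999        -1.24     43    1.89e- 1 0.440
```

The planted population (`pop02`) is ranked first: its 91 measured
signature genes average a 3.48-fold elevation, 90 of 91 are up (Fisher
p = 1.1e-22 against a null band centered at ~50%), the rank-sum bias is
55 orders of magnitude beyond chance, and its overlap AUC of 0.99 says
the signature genes sit essentially at the top of the fold-change
ranking.  The monocyte-like population (`pop01`), planted equally in
*both* old groups, correctly shows nothing in this contrast.  The curve
itself:

```r
oc <- overlap_curve(as_fc_vector(de), der$signatures$pop02)
oc
#> Cumulative overlap: 'pop02' (91 signature / 1730 background genes)
#> AUC = 0.9901 (AUC - 0.5 = +0.4901), rank-sum p = 4.14e-56
autoplot(oc)
```

`run_study()` wraps the whole workflow — four group contrasts plus the
interaction fit, DEG counts, genome-wide fold-change rank correlations,
enrichment tables, and the per-signature comparison of KO vs WT aging —
and can emit every table as TSV with a JSON run manifest.

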