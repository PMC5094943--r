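---
title: "Methods: moderated differential expression, signature derivation, and directional enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderated differential expression, signature derivation, and directional enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigshift)
options(sigshift.verbose = FALSE)
```

# The problem

Bulk expression profiles of a solid tissue mix signals from resident cells
with signals from infiltrating cell populations.  When a tissue ages, or a
genotype changes its immune environment, a substantial part of the observed
transcriptional shift can be a change in cellular composition rather than a
change in cell-intrinsic regulation.  sigshift detects such composition
shifts: it derives, from a labeled reference compendium of sorted cell
populations, a fixed-size set of *signature genes* specifically expressed
by each population, and then asks whether those signature genes are
collectively biased up or down in a fold-change vector from a bulk
comparison (old vs young, knockout vs wild-type, treated vs control).

The package was built around a 2x2 genotype-by-age liver study design
(two genotypes WT/KO, two ages young/old, unbalanced cell sizes), but
every function takes plain tabular inputs and applies to any comparable
two-group or two-factor design.

# Moderated differential expression

For a two-group contrast, each gene g is fit by least squares on log2
expression; the fold change is `FC = 2^(mean_A - mean_B)`.  With small
group sizes the gene-wise variance estimates `s_g^2` are unstable, so they
are shrunk toward a common prior with the standard empirical-Bayes
hierarchy: `s_g^2 ~ s0^2 * F(d_g, d0)`.  The hyperparameters `(d0, s0^2)`
are estimated by the closed-form moments method on log variances
(digamma/trigamma matching, with a Newton inversion of the trigamma
function), and the moderated variance is the convex combination

    s~_g^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)

The moderated t is the log2 fold change over its shrunk standard error,
with `d0 + d_g` degrees of freedom.  Two limits anchor the implementation
and are asserted in the tests: at `d0 = 0` the statistic equals the
ordinary pooled two-sample t, and at `d0 = Inf` it becomes a z-like
statistic with the common variance `s0^2` for every gene.  A third
property replaces a tempting but false monotonicity claim: moderation does
not uniformly increase |t|; rather the moderated variance always lies
between `s_g^2` and `s0^2`, so the moderated t lies between the ordinary t
and the common-variance z, gene by gene.  The implementation is also
cross-checked in the test suite against limma, the reference
implementation of this model, which the package deliberately does not use
in its own code path.

The genotype-by-age interaction is fit as a two-factor cell-means model;
the interaction coefficient is the aging log2 fold change in KO minus the
aging log2 fold change in WT, pooled-variance moderated exactly as above.
Contrasts are fit as independent two-group models per comparison rather
than one omnibus model, because the detection filter is applied per
comparison (below) and the included gene set differs between contrasts.
BH adjustment is per contrast, over included genes only.

## Detection filtering

Arrays report probe-level perfect-match/mismatch intensity pairs.  A probe
set is called *above background* in a sample when a one-sided Wilcoxon
signed-rank test of PM - MM > 0 gives p < 0.05, and a gene is detected
when at least one of its probe sets is.  A gene enters a comparison when
it is detected in at least one third of the comparison's samples.  "At
least one third" is ambiguous when n is not divisible by 3; the
implemented rule is a detected count of at least `ceiling(n/3)` (so 4 of
10), which is the literal "at least n/3" reading.  The fraction is
configurable.  Genes excluded by the filter remain in the result table
with an explicit `included = FALSE` flag rather than disappearing.

## DEG thresholds

Default DEG calls require FDR < 0.10 together with linear FC > 1.50 or
FC < 0.67.  The inequalities are strict: a gene at exactly FC = 1.50 is
not called.  Thresholds are applied on the linear FC scale, with the FC
always derived as `2^(difference of log2 means)`.

# Two-stage signature derivation

Signatures are derived per population from a one-vs-rest moderated
contrast against all other compendium samples pooled:

1. keep genes with FC > 1 (elevated in the population);
2. of those, keep the `n_p = 150` with lowest p-value;
3. of those, keep the `n_sig = 100` with highest FC.

The decreased-expression variant (for treatment signatures built from
down-regulated genes) mirrors the procedure with FC < 1 and lowest FC in
stage 3.  An optional candidate restriction is applied before stage 2,
for workflows that pre-filter to an FDR-based DEG list.  Fixing the
signature size equalizes populations: raw DEG counts vary by orders of
magnitude across cell types, and a fixed-size FC/p ranking makes
enrichment statistics comparable across the collection.

Tie-breaking is not specified by the procedure itself and was chosen for
determinism: stage-2 ties at the p cutoff are broken by larger |log2FC|
then lexicographic gene id; stage-3 ties at the FC cutoff by smaller p
then gene id.  If fewer than `n_sig` genes survive stage 1, all survivors
are returned and the result is flagged short.  Selection is idempotent
and invariant to sample and row order; both properties are tested.

# Directional enrichment statistics

Given a fold-change vector and a signature, three statistics are
computed.  The background is always the measured non-signature genes,
not an abstract universe; signature genes absent from the vector are
dropped with a logged count (no imputation).

**Rank-sum bias.**  A two-sided Wilcoxon rank-sum test compares log2 fold
changes between signature and background genes.  The p-value is reported
as a signed log10 p: `-log10(p)` carrying the sign of (median signature
log2FC - median background log2FC), so positive values mean the signature
is biased toward increased expression.

**Direction counts.**  Each gene is dichotomized as up (FC > 1) or down
(FC <= 1; a tie at exactly 1 counts as down by default, configurable),
and the 2x2 signature/background x up/down table is tested with Fisher's
exact test (two-sided, probability-sum convention).  The middle 95% of
the hypergeometric null for the signature's up-count is returned so the
observed count can be drawn against its null band.

**Cumulative overlap AUC.**  Genes are ranked by log2 fold change
(descending by default; ties broken by gene id) and the cumulative
recovery of signature genes is traced.  The AUC is computed on the
unit-square curve with the background fraction on x and the signature
fraction on y, by trapezoid, with tied blocks contributing diagonal
segments.  Under this convention the AUC equals the Wilcoxon-Mann-Whitney
`U/(n1*n2)` exactly (to 1e-9 on tie-free data, an acceptance check), 0.5
is no enrichment, and 1 is maximal.  A rank-axis curve of raw cumulative
counts is also emitted for figure-style plotting.  The rank-sum p-value
accompanies `AUC - 0.5` as its significance.

`rank_signatures()` applies all three to a signature collection and sorts
by signed log10 p; given a second fold-change vector it reports the
per-signature difference in signed log10 p (e.g. KO aging vs WT aging),
sorted by that difference.

# Statistical kernel conventions

* Rank-sum: mid-ranks for ties; exact enumeration when the combined
  sample size is at most 12 and tie-free, otherwise normal approximation
  with tie-corrected variance and continuity correction.  The exact
  switch point is a desk-scale choice, configurable per call.
* Signed-rank: zeros dropped; exact enumeration (dynamic programming
  over sign patterns, mid-ranks allowed) up to 15 non-zero differences,
  normal approximation beyond; all-zero input returns p = 1 flagged
  degenerate.
* Fisher 2x2: two-sided p sums the probabilities of tables no more
  probable than the observed one — the convention of mainstream
  implementations, stated explicitly because the doubling convention
  differs.
* Hypergeometric enrichment is the plain upper tail.  An ontology DAG is
  out of scope; as the closest in-scope analogue of
  ontology-conditional testing, `hypergeom_enrich_sets()` accepts a
  parent-to-children map and removes hit genes of significant children
  from a parent's set before testing the parent, in one pass.
* BH adjustment is the textbook step-up with monotonicity enforcement,
  delegated to `p.adjust`.
* Exact paths are verified against independent brute-force enumeration
  oracles in the test suite (all instances with combined n <= 10 for the
  rank-sum, n <= 12 for the signed rank, grand total <= 30 for Fisher).

## Protected LSD and letter displays

The qPCR workflow reports group differences with Fisher's least
significant difference.  The protected (textbook) variant is the
default: pairwise pooled-MSE t-tests are only declared significant when
the omnibus one-way F-test rejects at alpha; with `protect = FALSE` the
gate is disabled.  Letters are assigned by insert-and-absorb so that two
groups share a letter exactly when their pairwise LSD p is at or above
alpha; the partition is invariant to input order.

The ANOVA is run on dCt values by default.  The Ct scale is closer to
log-normal homoscedastic, so dCt is the variance-stabilized choice; the
relative-expression scale (`2^-ddCt`) is supported via `scale =
"relative"` for workflows that prefer to test the reported quantity.
Relative expression is normalized so the calibrator group's mean is
exactly 1 on the linear scale.

# The synthetic-data generators

The generators produce every input the pipeline consumes, with recorded
ground truth, and their defaults are the study conditions the package is
validated under:

* **Design**: cell sizes young-WT 5, young-KO 5, old-WT 6, old-KO 8 —
  the unbalanced 2x2 design of the motivating study.
* **Compendium**: 5 populations x 3 replicates at 2000 genes by default
  (a desk-scale stand-in for a 222-population, ~3-replicate reference),
  with 100 disjoint planted markers per population at +2 log2 units.
* **Gene variances** are drawn from the scaled inverse-chi-square prior
  (`d0 = 4`, `s0^2 = 0.05`) under which empirical-Bayes shrinkage is
  exactly specified, so the moments estimator is well-posed and null
  p-values are uniform by construction.
* **Baselines** are a two-component mixture: ~85% expressed genes around
  log2 intensity 7 (sd 1.5) and ~15% near-background genes around 3,
  the latter flagged undetected in a random 70% of samples so the
  detection filter has genuine work.
* **Infiltration** is additive on the linear scale: sample = host signal
  + weight x population profile, then re-logged.  This is the mixture
  mechanism the composition-shift interpretation assumes, and it makes
  marker fold changes respond sub-linearly to the mixing weight
  (`log2(1 + w * 2^profile_effect)`), as in real mixtures.  Only the
  marker complement of a population contributes to the profile: the
  uniform whole-transcriptome component of a real cell mixture is a
  global compositional shift that upstream normalization (the matrices
  this package ingests are normalized) removes, so simulating it would
  only inject an artifactual DC offset.
* **Preset scenarios**: `infiltration` plants monocyte-like infiltration in all
  old samples plus B-cell-like infiltration in old-KO only (weights 0.10
  and 0.15); `steatosis` plants a WAT-like profile whose weight rises with
  age from 0.01 to 0.15 in WT but only to 0.04 in KO.  No published
  effect-size estimates exist for these weights; they are synthetic
  calibrations chosen once to reproduce the qualitative patterns
  (target population ranks first; WT aging AUC exceeds KO aging AUC)
  at realistic noise, and are not estimates of any real mixture
  fraction.

What the generators do *not* emulate: probe-level CEL structure, batch
and chip effects, inter-gene correlation beyond the planted structure,
platform mapping between array generations, and compositional
renormalization.  Passing the recovery tests therefore shows the
machinery is correct and calibrated under the stated model, not that any
particular biological dataset will behave as cleanly.

# Numerical and design choices

* Expression values are assumed log2 on input; files are plain TSV
  (genes x samples), GMT for gene sets.  Gene matching is exact-string.
* All randomness flows through a single integer seed per generator call;
  the caller's RNG state is saved and restored, and identical seeds give
  byte-identical serialized output (tested).
* `signed_log10p` clamps p = 0 at the smallest positive double with a
  warning rather than returning infinity.
* Degenerate inputs are flagged, not silently absorbed: all-tied rank
  data give p = 1 with a degenerate method tag, constant vectors make
  the rank correlation NA with a warning, an all-zero within-group
  variance makes the LSD error.
* Problem sizes in the validation suite (2000-5000 genes, 5
  populations, 20-seed recovery loops) were chosen as the smallest
  scales at which the calibration and recovery properties are sharp;
  all scale linearly if increased.

# Reproducing the validation numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
validation quantity from scratch: staged selection sizes, exact-test and
AUC/U maximal deviations, null calibration rates, 20-seed recovery rates
for both preset scenarios, the realized false-discovery proportion, and
the analytic-limit deviations of the moderated t.  The test suite runs
the same checks with fixed tolerances.

# Known limitations

* The enrichment tests treat genes as exchangeable under the null;
  inter-gene correlation (co-regulation within a signature) is not
  corrected for, so p-values on real data are anti-conservative to an
  unknown degree — the ranking across signatures is the robust output.
* Signature quality inherits the reference compendium's quality; the
  derivation cannot detect label errors or platform effects in the
  reference.
* The detection filter needs probe-level PM/MM data or a precomputed
  detection matrix; for platforms without mismatch probes, supply your
  own detection calls.
* One-pass conditional set enrichment is a shallow analogue of
  ontology-aware conditional testing and does not traverse a DAG.
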