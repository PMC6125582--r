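---
title: "Methods: co-expression module discovery and trait association with coexmod"
author: "coexmod authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression module discovery and trait association with coexmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

# The analysis problem

Single-gene differential-expression tests in psychiatric transcriptomics are
underpowered: effects are small, dispersed, and interact. `coexmod`
implements a module-level alternative for bulk RNA-Seq of a case/control
cohort with a quantitative severity phenotype (the motivating use case is
peripheral-blood RNA-Seq of depressed and healthy participants rated on the
MADRS, the Montgomery-Åsberg Depression Rating Scale). Genes are grouped
into data-driven co-expression modules, each sample's transcriptome is
collapsed to one enrichment score per module, and the handful of module
scores — rather than thousands of genes — are tested for association with
severity under false-discovery-rate control. Discovered modules can then be
scored in an independent cohort, because the per-sample score depends only
on that sample's expression ranks.

The pipeline is: preprocessing → hard-thresholded unsigned correlation
network → topological-overlap dissimilarity → average-linkage clustering
with an adaptive tree cut → single-sample gene set enrichment (ssGSEA)
scores → covariate-adjusted linear models with Benjamini-Hochberg (BH)
adjustment → centrality/hub analysis → replication.

# Preprocessing

**Low-count filter.** A gene is kept when at least `min_samples` (default
15) samples support it with enough reads. "Enough" depends on the sample's
library size: the per-sample read threshold interpolates linearly over
library-size rank from 2 (smallest library) to 7 (largest), rounded to the
nearest integer. The linear-in-rank rule is this package's
operationalization of a "2–7 reads depending on library size" criterion; a
CPM cutoff was rejected as further from the read-count phrasing. The filter
is idempotent.

**Normalization.** Expression is log2 counts per million with a prior count
of 0.5: `log2((count + 0.5) / (libsize + 1) * 1e6)`. Full conditional
quantile normalization additionally adjusts for GC content and gene length,
but requires per-gene annotation; since every downstream stage consumes a
generic normalized matrix and the synthetic data carry no GC or length
structure, plain logCPM is used and documented as a deliberate
simplification. Trimmed-mean (TMM) normalization factors are computed by
`tmm_factors()` as a *diagnostic only* — outlying samples tend to show
extreme factors — and are never applied.

**Outlier samples.** The angle-based outlier factor (ABOF) of sample *p* is
the variance, over all unordered pairs *(x, y)* of other samples, of
`<p-x, p-y> / (|p-x|^2 |p-y|^2)`. Points far outside the data cloud see all
other points under a narrow cone of angles and get small ABOF. With ~160
samples the exact O(n³) computation is trivial (a Gram-matrix identity makes
it O(n³ + n² g)), so no k-nearest-neighbour approximation is used. Genes are
standardized first, and the standardized matrix is divided by the square
root of the gene count: this makes the ABOF magnitude independent of the
size of the gene universe, so that one absolute threshold (default `0.001`)
is meaningful across data sets; in simulated cohorts typical samples score
around 2e-3 and planted outliers one to two orders of magnitude lower.
Samples below the threshold are removed and logCPM is recomputed on the
retained samples' library sizes.

**Batch correction.** Per gene, expression is regressed on an intercept,
any covariates to preserve, and batch indicator contrasts; only the fitted
batch component is subtracted, after centring it so each gene's grand mean
is preserved exactly. An exactly confounded batch/covariate design is a
singular-design error, not a silent drop.

**Variability filter.** The coefficient of variation (COV = sample standard
deviation / mean) is computed per gene *on the unlogged CPM scale* — log-scale
means can sit near zero, making a log-scale COV unstable — and genes with COV
above 0.8 are removed as technically over-variable. Zero-mean genes are
removed with reason `"zero-mean"` rather than crashing. The provenance
record keeps every removed gene and sample with the rule that removed it, so
`genes in − removed(low count) − removed(COV) = genes out` holds on any run.

# Network construction and module detection

The adjacency is the absolute Pearson correlation (an *unsigned* network:
strong negative co-expression is as informative as positive), with an exactly
zero diagonal. Rather than the soft-threshold power transform common in
weighted co-expression analysis, a *hard threshold* τ zeroes all entries
below τ; surviving entries keep their weights by default (`binarize = TRUE`
is available — the methodology literature is ambiguous on this point, and the
weighted variant preserves more information).

The clustering dissimilarity is one minus the topological overlap:

TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),

with `l_ij = Σ_u a_iu a_uj` and `k_i = Σ_u a_iu`. Two genes are similar when
they are directly connected *and* share neighbours, which denoises the raw
correlation graph. A non-positive denominator (an isolated mutually
connected pair) is mapped to TOM = 0 — maximal dissimilarity — with a logged
warning; values are clamped to [0, 1] against floating-point drift.

**Adaptive tree cut.** Genes are clustered by average linkage (UPGMA), the
standard companion to TOM dissimilarity; a fixed-height cut cannot separate
modules that sit at different depths of the dendrogram, so modules are read
off the tree shape:

1. a static cut at `cut_height_quantile` (default 0.99) *of the maximum
   merge height* gives the initial branches. The fraction-of-height
   convention (rather than a sample quantile of the merge heights) is
   deliberate: after hard thresholding, background genes merge at exactly
   d = 1, so a sample quantile would coincide with the maximum and collapse
   the tree into one cluster;
2. each branch is split recursively. Under average linkage the merge height
   of a node *is* the mean dissimilarity between its two sub-branches, and
   the mean within-branch dissimilarity can be maintained incrementally, so
   each node carries an exact between/within contrast
   `(h − max(w1, w2)) / (h_max − max(w1, w2))`. A node splits when this
   contrast exceeds `split_gap` (default 0.3) and both sub-branches contain
   at least `min_module_size` genes. Splits found deeper in a branch
   propagate upward through chained or equal-height merges (an undersized
   side branch is carried along as its own piece), which matters in
   realistic dendrograms where modules join through chains of background
   genes rather than at a single clean node;
3. branches below `min_module_size` (default 30, below the smallest module
   one expects to interpret) are merged into the nearest branch by average
   dissimilarity when that distance lies within the cut height, otherwise
   labelled 0 (unassigned). Labels are renumbered by decreasing size.

The `split_gap` default was calibrated once on simulated block dissimilarity
structure: true module boundaries show contrasts around 0.5–0.75, spurious
within-module splits around 0.1, so 0.3 sits between the two populations
with margin on both sides. No expression-data reassignment stage (as in the
"hybrid" variant of dynamic tree cutting) is used.

**Threshold tuning.** The full detection stage is repeated over a τ grid and
the τ whose mean nonzero-module size is closest to a target (default 200
genes — the scale at which gene set enrichment is typically effective, and
similar sizes limit module-size bias in scoring) is selected, ties going to
the smaller τ. A report of module count and size distribution per grid point
is returned for inspection.

# Module scores (ssGSEA)

For one sample, genes are ranked by expression (descending, ties broken by
stable gene-id order for reproducibility). Walking down the list, the score
accumulates the difference between the weighted empirical cumulative
distribution of the module's genes (weights are bottom-ranks raised to
α = 0.25, the conventional exponent of the single-sample GSEA methodology)
and the unweighted ECDF of the remaining genes. The result measures how
coordinately the module's genes are up- or downregulated in that sample.
Scores across the cohort are divided by the global max−min range
("range-normalized"); per-sample standardization was rejected because it
would break the replication use, where scores must be computable on an
external cohort in isolation.

Two properties worth knowing:

* scores are invariant to any monotone per-sample transform of expression —
  only ranks matter, which is what makes cross-cohort application sound;
* for α > 0 the score of a *random* gene set is slightly positive on
  average (the weighted running ECDF telescopes to the r^α-weighted mean
  bottom-rank of the set, which exceeds the unweighted complement mean; at
  α = 0 the expectation is exactly zero). The shift is constant in
  expectation across samples, so the range normalization and the intercept
  of the downstream regressions absorb it; it should not be interpreted as
  enrichment.

# Trait association

The severity trait is z-scored (`scale_trait()`); "scaled" severity is
interpreted as the sample z-score since no scale range is prescribed. Per
module, ordinary least squares regresses the scaled trait on the module
score plus covariates (sex, age, BMI, and batch by default; factors enter as
indicator contrasts; listwise deletion for missing covariates). The module
coefficient, its standard error, the two-sided t-test p-value and the
BH-adjusted p-value (adjusted within the module family only) are reported,
along with each model's BIC from the full-sample likelihood.

Two sensitivity analyses mirror common practice: adding smoking status as a
covariate and comparing the models by BIC (`compare_bic()`, smaller BIC
wins, ties keep the original), and re-fitting on a sample subset such as a
single ancestry stratum (`subset_sensitivity()`).

Because ssGSEA scores are relative within a sample, a strong trait-coupled
module mechanically depresses the scores of other modules; with few modules
this compensation can make one or two additional modules weakly significant
with the opposite sign. This is a property of rank-based single-sample
scoring, visible in the synthetic studies, and worth remembering when
interpreting borderline discoveries.

# Centrality and hub genes

On the tuned thresholded adjacency (the same network the modules were cut
from), eigenvector centrality is the entrywise non-negative principal
eigenvector, computed by power iteration to relative tolerance 1e-10 on the
largest connected component (zeros elsewhere, with a warning listing
component sizes). A positive diagonal shift of 0.1 × max connectivity is
applied before iterating: it leaves the eigenvectors unchanged but makes the
principal eigenvalue strictly dominant — without it the iteration oscillates
on bipartite graphs (a 3-node path has eigenvalues ±√2).

Gene-level importance is `s = −log(BH-adjusted p)` (natural log) from a
logistic regression of diagnosis on each gene; perfect separation falls back
to a likelihood-ratio test and is flagged. Per module, the R² of importance
on centrality quantifies the "hub genes matter more" signal, and a
hypergeometric upper tail (inclusive, `P(X ≥ x)`) tests whether the module
is over-represented among the top 100 most significant genes.

# Replication

`restrict_modules()` intersects each discovered module with the external
cohort's gene universe and reports per-module overlap (modules falling below
10 retained genes are flagged). `replicate_modules()` then computes ssGSEA
scores of the restricted sets over the external cohort's own post-filter
universe — no quantity from the discovery cohort enters — and fits logistic
regressions of diagnosis on each score with sex, age and BMI as covariates
(batch is typically unavailable externally). No multiplicity adjustment is
applied across the small replication family.

# The synthetic-cohort generator

`generate_cohort()` draws the data the analysis assumes, with known truth:

* per-module latent factors f_m ~ N(0,1) per sample; gene g in module m has
  log-mean `b_g + σ_g (√ρ f_m + √(1−ρ) ε)` — a Gaussian copula in which one
  parameter ρ (`within_module_correlation`) controls the within-module
  correlation — with baselines `b_g ~ N(log 100, 1)` and gene scales
  `σ_g ~ U(0.3, 0.5)`, chosen so that typical genes pass a COV-0.8 filter
  (observed logCPM within-module correlation ≈ 0.22 at ρ = 0.6, verified
  against an independent Monte-Carlo oracle in the test suite);
* counts are negative binomial (`size = 1/nb_dispersion`, default
  dispersion 0.15) around `exp(log-mean) × library factor`, with log-normal
  library factors (CV ≈ 0.3) so the library-size-dependent low-count rule is
  actually exercised;
* the MADRS-like trait is
  `10 + trait_effect × Σ(trait-module factors) + 0.05(age−32) + 0.15(BMI−28)
  + N(0, 6²)`, truncated at zero and rounded — matching the scale's
  integer, zero-floored range; diagnosis thresholds a noisy liability built
  from the raw trait, so diagnosis and severity are correlated as in a
  clinical case/control sample;
* batch offsets are per-batch, per-gene N(0, `batch_sd`); a fraction of
  genes gets a log-mean of log(0.1) (guaranteed low-count failures) and a
  fraction gets σ inflated to 1.1–1.5 (guaranteed COV failures), both drawn
  from the background so planted modules stay intact; `n_outliers` samples
  are shifted by `outlier_shift` gene-scale units in half the genes;
* all sub-stages draw from deterministic child seeds of one global seed, so
  cohorts are byte-for-byte reproducible.

`generate_replication_cohort()` rebuilds an independent cohort over a
reduced universe that retains only `overlap_fraction` of each module's genes
(emulating differing low-abundance filters between studies) and couples
diagnosis to the trait-module factors through a logistic liability.

**What the generator does not emulate:** GC-content and gene-length biases,
read-level structure, antisense/natural-antisense transcripts, cell-type
mixture shifts, and correlated batch-by-module confounding. Passing tests on
synthetic cohorts therefore demonstrate that the machinery recovers the
structure it models — not that real cohorts satisfy that model.

# Numerical choices and degenerate inputs

* TOM denominators ≤ 0 → TOM 0 with a warning; TOM clamped to [0, 1].
* Dendrograms with all-zero heights (identical genes) → a single module.
* ssGSEA requires a non-empty strict subset of the universe; a module with
  no genes in the expression matrix yields an `NA` column plus a warning
  (the replication path tolerates it).
* Ties in expression break by gene id; ties in the τ objective break toward
  the smaller τ; BIC ties keep the first (original) model.
* Zero-variance genes are an error in the correlation step (they should
  have been filtered) but are handled gracefully in the univariate
  importance scan (p = 1, s = 0).
* Perfectly separating genes use a likelihood-ratio fallback.
* Contingency tables drop zero-margin rows/columns with a warning; the
  Yates-corrected statistic clamps at zero. For 2×2 tables both the
  corrected and uncorrected statistics are reported, since published tables
  rarely say which was used — in the motivating study's Table 1 the sex row
  is reproducible only *with* the correction and the smoking row only
  *without* it.

# Problem sizes in the test suite

The packaged studies run at reduced but structurally faithful scale, chosen
so the whole suite completes in a few minutes: module-recovery studies use
157–160 samples × 900–1,200 genes with five planted modules of 100–200 genes
(adjusted Rand index ≥ 0.7 required in at least 8 of 10 seeds; observed
≈ 0.92–0.95); association calibration uses 200 null seeds (family-wise
any-discovery ≤ 0.07) and 50 strong-effect seeds (both trait modules
flagged in ≥ 80%; observed 100%); outlier detection uses 50 seeds of
80 × 400 cohorts (planted outliers must receive the minimum ABOF in ≥ 90%;
brute-force equality is checked exactly on ≤ 30 samples). Exact-arithmetic
oracles (TOM, ssGSEA, BH, eigencentrality) are checked to 1e-10 or better.

# Known limitations

* logCPM in place of GC/length-aware normalization (above).
* The adaptive tree cut is a shape-based top-down procedure; it has no
  expression-level gene reassignment stage, so genes weakly attached to a
  module's periphery may be left unassigned or absorbed by a neighbouring
  branch. Observed module sizes run ~15–25% above planted sizes because
  connected background genes are absorbed at the merge step.
* ssGSEA's within-sample compensation (above) can produce weak
  opposite-signed discoveries next to a strong true module.
* The replication stage assumes the external cohort is already reduced to a
  comparable post-filter gene universe; it applies the low-count and COV
  filters but no cross-cohort normalization.
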