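---
title: "Methods: building and applying cell-type DNAm reference matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and applying cell-type DNAm reference matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdecon)
```

# The problem

Bulk DNA methylomes are averages over the cell types in a tissue, which
confounds disease comparisons and hides cell-type-specific signal.
Reference-based deconvolution resolves this, but requires a DNAm reference
matrix — expected promoter beta values for marker genes across the tissue's
cell types — and such references do not exist for most solid tissues.
`methdecon` implements two routes to a reference and the full downstream
machinery:

1. **Imputation from scRNA-seq.** Cell-type marker genes are identified in an
   annotated scRNA-seq dataset; for the subset whose promoter methylation is
   demonstrably anticorrelated with expression (in two independent matched
   DNAm/expression compendia), promoter DNAm is imputed from the expression
   pattern.
2. **Direct derivation from single-nucleus methylomes**, where available,
   by coverage filtering, promoter aggregation and AUC-ranked marker
   selection.

Either reference feeds a weighted robust regression (wRPC) that estimates
per-sample cell-type fractions, which in turn support cell-type-specific
differential-methylation calling (interaction models), locus-enrichment
tests, and derived scores (tumor purity, immune fraction, phenotype
proxies).

# Models and procedures

## Promoter summarization

Bulk array data arrive as probe-level betas. Each gene's promoter beta per
sample is the mean over its TSS200 probes (CpGs within 200 bp upstream of
the transcription start site); a gene without TSS200 data falls back to its
first-exon probes, and genes with neither are omitted. Missing probe values
are excluded from the mean, never treated as zero. When a probe maps to the
same gene under both classes, TSS200 wins — the fallback is strictly
ordered. Probes mapping to several genes are replicated into each gene's
set; the alternative (exclusive assignment) would need an arbitrary owner
choice that array annotations do not support.

## Marker selection and the expression reference

With K cell types, each gene is tested one-vs-rest by Wilcoxon rank-sum
(alternative: greater in the target type). Because scRNA-seq counts are
heavily tied at zero, we use the normal approximation with tie correction
throughout rather than exact enumeration. The marker specificity score
(MSS) is the number of *other* types whose median expression of the gene is
zero, so an ideal marker scores K − 1. Markers require BH-FDR < 0.05 and
MSS at the threshold; when fewer than 100 markers survive, the MSS
threshold is relaxed stepwise by 1, stopping at `ceiling((K-1)/2)` — a
schedule we fixed because some relaxation is clearly needed for small K but
an unbounded one would admit non-specific genes. A gene's target type is
the type with maximal median expression (ties broken by smaller Wilcoxon p,
then lexicographic type name, so outputs are deterministic). The reference
entry (g, k) is the median expression of g over cells of type k. Fewer
than 100 markers triggers a warning, not an error.

Validation assigns every cell of an annotated hold-out dataset a fraction
vector by unweighted robust partial correlations against the reference and
scores arg-max accuracy — our operationalization of "validation accuracy";
cells of types absent from the reference still receive an arg-max label and
can only be flagged by a low maximal fraction.

## Imputation of the DNAm reference

A marker is *imputable* when the Pearson correlation between its promoter
beta and its expression is at most `rho_max` (default −0.3) in **both**
matched compendia; requiring two independent datasets at a modest threshold
is a conservative reading of "strong anticorrelation", and the threshold is
exposed as an argument. For an imputable marker:

- in cell types where the expression reference is positive, the promoter is
  taken to be unmethylated: imputed beta exactly 0;
- in cell types where the gene is unexpressed, the imputed value is the
  mean of the **high-methylation component** of a two-state gamma mixture
  fitted to the gene's compendium betas, restricted to compendium samples
  where the gene is unexpressed. "Unexpressed" is operationalized as the
  lower tertile of that gene's expression across compendium samples — the
  cut must adapt per gene because compendium expression scales vary, and a
  tertile keeps enough samples for the mixture fit.

The per-marker confidence weight is the mean imputed beta over the cell
types that do not express the marker, clipped to [0, 1]: a marker whose
promoter really is methylated where it is silent carries information, one
imputed near zero everywhere does not. Markers expressed in every type get
weight 1 (no evidence against them).

## Two-state gamma mixture by EM

Betas (shifted from zero by epsilon = 1e-4, since the gamma support is
open at zero) are modeled as a mixture of two gamma densities fitted by EM:
E-step responsibilities from log densities with the log-sum-exp trick,
M-step by weighted gamma maximum likelihood (Newton iterations on the
shape). Initialization splits the data at the median with per-half
method-of-moments estimates; optional seeded random restarts keep the best
log-likelihood. Components are ordered by mean, so component 2 is the
high-methylation state by convention. Identical inputs are rejected as
degenerate. During imputation, a fitted "high" component whose mixing
weight is below `min_component` (default 0.1) is treated as upper-tail
noise rather than a genuine second state and the mixture mean is imputed
instead; without this rule the EM happily carves a tiny pseudo-component
out of the tail of unimodal data and biases the imputed value upward.

## Weighted robust deconvolution (wRPC)

Per sample, the bulk marker-beta vector is regressed without intercept on
the K reference columns; the reference columns span the mean structure, and
the coefficients are fraction-like, so an intercept has no place in the
model. The loss is Huber's M-estimator (tuning constant 1.345, the standard
95%-efficiency choice; the estimator is named in the underlying method but
no constant is, so we take the default the robust-regression literature
uses) with the per-marker weights as observation weights; `robust = FALSE`
switches to weighted least squares. Negative coefficients are set to zero
and the remainder rescaled to sum to one; if nothing is positive, the
sample gets a documented all-zero row and a warning. Missing bulk values
drop that marker for that sample only — per-sample regressions are
independent. When the least-squares residuals are (numerically) zero the
Huber IRLS has no scale to estimate and the LS solution is returned
directly; the two estimators coincide in that limit. Identical reference
columns are a hard error naming the collinear cell types.

The robustness that motivates the Huber loss is quantified by
`corruption_tolerance()`: with a 6-type, 600-marker block reference and 200
noiseless Dirichlet(1) mixtures, replacing a fraction q of reference
entries with Uniform(0, 1) noise leaves the minimum per-type correlation
between true and estimated fractions above 0.8 up to large q — the
"voting" behavior of multivariate inference over many markers.

## Cell-type-specific differential methylation

Per site c, ordinary least squares fits

$$\beta_c = \sum_{k=1}^{K} \mu_{ck}\, \hat f_k
  + \sum_{k=1}^{K} \beta^{(I)}_{ck}\, \hat f_k\, y
  + \gamma\, \mathrm{Age} + \rho\, \mathrm{Slide} + \varepsilon$$

with no global intercept: the fraction terms sum to one across each sample
and absorb it, which is also why all K fraction terms can be kept without
collinearity. Categorical covariates are one-hot encoded dropping one
level. The interaction t-statistics are converted to BH-FDR **per cell
type** across sites (counts are reported per type, so pooling would mix
different null scales), and a site is a DMCT in type k when FDR < 0.05,
hypermethylated in cases if the interaction coefficient is positive.
Near-zero fraction variance in a cell type yields a collinearity warning
rather than an error. Locus enrichment of a DMCT set uses the one-tailed
hypergeometric (Fisher) tail over a declared background universe; the
reported odds ratio is the sample odds ratio ad/bc.

## Single-nucleus reference derivation

Sparse Bernoulli CpG calls are filtered to CpGs covered in at least 5
nuclei, then averaged per gene promoter (TSS200 CpG map) within each
nucleus; entries with no covered CpG stay missing. Per cell type, genes
with at least 10 non-missing target values are Wilcoxon-tested for *lower*
methylation in the target type, and significant genes (BH-FDR < 0.05) are
ranked by AUC — computed from the Mann–Whitney U with tie correction,
oriented so that AUC near 1 means lower promoter DNAm in the target type,
i.e. permissive of expression. The top 20 per type are kept; the reference
entry is the mean beta over each type's non-missing nuclei, with unit
weights. The mitochondrial-cytosine read filter applied upstream in typical
processing is treated as QC outside our scope (a pass-through site filter
is available).

Two references are compared over shared (gene, type) entries by median
absolute deviation and Pearson correlation, with significance from a
gene-row permutation null (permuting rows rather than entries preserves
each type's marginal distribution). Monte-Carlo p-values use the add-one
rule \(p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{mc})\), so p is
never zero; when the number of shared genes is small enough that all
permutations fit in the budget, the null is enumerated exhaustively
(identity included) and p is exact.

## Derived scores

Tumor purity is one minus the summed fractions of the user-declared stromal
group (typically all immune cells, endothelial cells and fibroblasts),
clipped to [0, 1] — rounding can push a stromal sum marginally above one,
and a negative purity has no meaning. The immune score is the summed immune
fractions. Groupings are configuration, not hard-coded, because the stromal
definition is tissue-specific. Phenotype proxy panels screen pre-computed
two-phenotype expression markers for consistent promoter hypermethylation
(beta > 0.6) in at least 3 of the tissue's other cell types, which protects
the proxy from confounding by those types; the proxy score is the mean
TSS200 beta over the panel, and because the panel genes mark phenotype A,
a higher proxy means a *lower* phenotype-A fraction — the sign convention
is stored in the panel object.

# The synthetic-data module

Every input kind is generated with known ground truth so the full pipeline
is testable without external downloads. The default regime is brain-like:
K = 6 cell types, 100 markers per type, 90% nucleus-level missingness
(coverage 0.1), Dirichlet(1) mixing fractions, additive truncated-Gaussian
beta noise with sd 0.05, 200 mixtures, 200 EWAS samples. Generators are
pure functions of configuration and seed.

What the generators emulate — and what they do not:

- scRNA-seq counts are negative-binomial with block-structured marker
  expression (true MSS = K − 1 by construction); there is no batch
  structure, ambient RNA, or doublets, so passing marker-recovery tests
  says nothing about annotation quality in real atlases.
- Matched compendia plant a logistic decay of promoter beta with
  expression for the anticorrelated genes, with per-gene silent-state betas
  drawn from a high-mean gamma component (mean 0.8); real compendia have
  correlated samples and technology effects the simulation omits.
- Bulk mixtures are exact linear mixes plus clipped Gaussian noise;
  clipping rather than honest truncation distorts moments negligibly at
  sd ≤ 0.05, which is why we accept the simpler scheme.
- The nucleus simulator draws Bernoulli calls at the reference beta with
  i.i.d. coverage; real snmC-seq coverage is correlated along the genome.
- The EWAS generator realizes the interaction model's Gaussian error term
  directly. Planted-site baselines are drawn low enough that adding the
  interaction effect cannot clip at beta = 1 — otherwise clipping silently
  attenuates planted effects and sensitivity estimates are biased downward.
  Effects can be planted in one concentrated cell type (the typical disease
  pattern, where a single cell type dominates the differential signal) or
  scattered at random (the default).

# Numerical choices and problem sizes

- Huber IRLS: max 50 iterations, coefficient tolerance 1e-8; LS fallback at
  zero residual scale.
- EM: convergence at log-likelihood change < 1e-8, cap 500 iterations;
  zero-shift epsilon 1e-4; component order by mean.
- Ties in all rank statistics: average ranks with the tie-corrected normal
  approximation and continuity correction.
- Deterministic tie-breaks everywhere a choice is arbitrary (marker target
  type, AUC ranking by AUC then p then gene name).
- TSV is the canonical format (full double precision on write, so round
  trips are exact at 10 significant digits); MTX triplets are accepted for
  sparse expression; groupings are YAML.

The shipped test-suite simulations use 200 samples / 2,000 sites for the
interaction-model operating characteristics, 200 mixtures from a 600-marker
6-type reference for fraction recovery, 600 nuclei at 90% missingness for
the single-nucleus pipeline, and a 0.05-step corruption grid with 10
replicates for the corruption-tolerance analysis — sizes chosen to make the
statistical assertions stable at desk scale.

# Known limitations

- Imputation is promoter-centric; enhancer methylation is out of scope, so
  marker panels are limited to the 10–30% of markers that show promoter
  anticorrelation, and closely related subtypes may remain hard to
  distinguish.
- Estimated fractions are best interpreted as relative quantities,
  comparable across samples for a given cell type; that is the property the
  downstream regression models require.
- The univariate hypomethylation test, not the multivariate fraction
  estimator, is the right tool at single-nucleus sparsity (>90% missing);
  `estimate_fractions` on individual nuclei is not supported by design.
- The multi-set intersection significance of DMCT overlaps is not
  implemented; pairwise Fisher overlap is.
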