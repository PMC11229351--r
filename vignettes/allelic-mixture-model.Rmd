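---
title: "Modelling spatial allele-specific expression with cell-type mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial allele-specific expression with cell-type mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelemix)
```

## The problem

In spatial transcriptomics of an F1 hybrid, a fraction of UMIs can be
assigned unambiguously to the maternal or the paternal allele of a gene.
Mapping where in a tissue a gene is expressed preferentially from one
allele — allele-specific expression (ASE) — is complicated by two features
of these data. First, a measurement spot (a bead or capture area) mixes
transcripts from several cells, often of different cell types, and cell
types differ both in how much of a gene they express and, potentially, in
its allelic bias; spatial and cell-type effects are therefore confounded.
Second, at near-single-cell resolution the allele counts are strongly
overdispersed relative to binomial sampling — the spatial face of
"transcriptional bursting" — so binomial-based tests would be wildly
anticonservative.

`allelemix` addresses both with a beta-binomial mixture model fitted per
gene, a four-category hypothesis-testing suite, surface estimation with
confidence intervals, and a simulation framework for validating the
machinery.

## The model

For gene $j$ at spot $i$ with 2D coordinates $x_i$, let $Y_{ij}$ be the
maternal allele count and $N_{ij}$ the total allele-resolved count. We
assume

$$Y_{ij} \sim \text{BetaBinomial}(p_{ij},\, N_{ij},\, \phi_j), \qquad
p_{ij} = \sum_{k=1}^{K} \alpha_{ijk}\,
  \operatorname{expit}\!\Big(\beta_{0kj} +
  \sum_{\ell=1}^{L} \beta_{\ell k j}\, \gamma_{i\ell}\Big),$$

where the beta-binomial is parameterized by its mean $p$ and an
overdispersion $\phi \in [0, 1)$, corresponding to a Beta$(a, b)$ mixing
distribution with $a = p(1-\phi)/\phi$ and $b = (1-p)(1-\phi)/\phi$;
$\phi \to 0$ recovers the binomial, and $\phi_j$ is shared across spots
and cell types within a gene. The covariates $\gamma_{i\ell}$ are
user-chosen; in non-parametric mode they are thin-plate spline basis
functions of $x_i$.

The mixture share $\alpha_{ijk}$ — the fraction of gene $j$'s transcripts
at spot $i$ contributed by cell type $k$ — is pre-computed from upstream
inputs: deconvolution proportions $w_{ik}$ and cell-type-specific
expression rates $\mu_{ijk}$,

$$\alpha_{ijk} = \frac{w_{ik}\,\mu_{ijk}}{\sum_k w_{ik}\,\mu_{ijk}}.$$

This follows from decomposing the expected maternal proportion at a spot
over the cell types sourcing the gene's transcripts. When no rate
estimates are available, `default_rates()` sets all rates to 1 so
$\alpha = w$; simulations in the test suite demonstrate that this
misattributes cell-type contributions when true rates are unequal, which
is why supplying rate estimates is preferred. Spots where the denominator
is zero (no cell type present expresses the gene) have an undefined
conditional probability and are excluded from that gene's likelihood.
Cell types whose total share over a gene's usable spots falls below a
floor (default 1.0, roughly "less than one spot's worth of transcripts")
are dropped from that gene's parameter set for identifiability, and the
remaining shares renormalized.

## Fitting

Each gene is fitted independently by maximum likelihood. The coefficient
step is a second-order trust-region Newton ascent: the quadratic model
built from the analytic gradient and Hessian (chain rule through the
mixture-of-expits mean, digamma/trigamma terms for the beta-binomial) is
solved exactly within the current radius via an eigendecomposition of the
Hessian, which handles the non-concavity of expit mixtures without line
searches. A step is accepted when the achieved improvement exceeds 0.1 of
the predicted improvement; the radius halves below ratio 0.25 and doubles
above 0.75. The overdispersion step maximizes the likelihood in $\phi$
alone by bounded scalar optimization on $[10^{-6}, 1-10^{-6}]$; the two
steps alternate until the joint log-likelihood changes by less than
$10^{-8}$ (at most 50 alternations, 200 Newton iterations per step —
engineering defaults exposed in `fit_control()`, flagged when hit).
Whether to fix $\phi$ first or alternate is not dictated by the model;
alternation is monotone in the likelihood and is the documented choice
here.

Initialization is $\beta = 0$ (every cell type at $p = 0.5$, the global
null) with a method-of-moments warm start for $\phi$. Linear predictors
are clipped to $[-15, 15]$ inside the expit: genes with complete
separation (e.g. all counts maternal) otherwise diverge; clipping events
are recorded as separation warnings. Coefficient covariance is the
inverse observed information at the optimum, treating $\phi$ as fixed
(standard generalized-linear-model practice); when the information matrix
is not positive definite, the smallest ridge from $10^{-8} \cdot 2^m$
that makes it invertible is added and recorded.

## The spline basis

The 2D smoother is a low-rank unpenalized thin-plate regression spline
built from scratch so the package is self-contained: coordinates are
standardized (centered, scaled by root-mean-square distance — undone at
evaluation), the radial kernel $r^2 \log r$ on pairwise distances is
eigendecomposed and truncated to its $k - 3$ leading directions, the
linear null space $(x, y)$ appended, and the constant direction absorbed
by a sum-to-zero constraint since the model supplies its own intercept —
leaving $L = k - 1$ columns. Only the constant is absorbed; the linear
terms remain in the span (the tests verify this). Eigenvector signs are
fixed (largest-magnitude component positive) so construction is
deterministic, and for large datasets the kernel eigenproblem is solved
on a deterministic space-covering subset of at most `max_knots` spots.
Columns are centered and scaled to unit variance over the training spots,
with the constants stored, so coefficients live on a common logit scale
and the truth-surface generator's coefficient standard deviation is
directly interpretable. No penalization is used: fits are fixed-df, and
exact numerical equality with any external spline implementation is not a
goal — the test suite instead checks agreement of fitted probability
surfaces with an independent `mgcv` fit on simulated data.

The defaults follow the two uses: $k = 5$ for hypothesis tests (few
degrees of freedom, well-calibrated likelihood ratio tests) and $k = 15$
for visualization surfaces of genes that already passed a test.

## Hypothesis testing

Four batteries, each per gene:

1. **Overall bias** — intercept-only model ignoring cell type and space;
   Wald test of $\beta_0 \ne 0$. A significant gene is called *maternal*
   only when $\hat p > 0.6$ and *paternal* only when $\hat p < 0.4$;
   significant genes between the bounds get no direction.
2. **Within-cell-type bias** — mixture intercept model
   $p_i = \sum_k \alpha_{ik}\operatorname{expit}(\beta_{0k})$; Wald test
   per retained cell type with the same direction rule on
   $\operatorname{expit}(\hat\beta_{0k})$.
3. **Overall spatial pattern** — likelihood ratio test of the $k = 5$
   spline model against the intercept-only model, $\chi^2_L$ reference,
   $\phi$ re-estimated in each model.
4. **Within-cell-type spatial pattern** — mixture model with cell-type
   intercepts and spline terms inside the expit, tested against the
   within-cell-type intercept model. By default the spline coefficients
   are shared across cell types (one test, df $L$); optionally each cell
   type carries its own block and is tested separately (df $L$ each) by
   refitting with that block pinned to zero. Both variants exist because
   either reading of the model is defensible; the shared form is the
   default.

Wald statistics are used for the single-coefficient tests and likelihood
ratio tests for the multi-coefficient spatial tests. Benjamini–Hochberg
correction is applied within each battery (and within cell type for the
within-cell-type batteries), matching how the result categories are
stratified; significance is $q < 0.01$. Numerically negative LRT
statistics (possible when two optimizations terminate at slightly
different tolerances) are floored at zero with a note. Genes need at
least 128 spots with non-zero totals to be tested overall, and 128
supporting spots per cell type (deconvolution weight $\ge 0.5$, i.e.
majority assignment) for the within-cell-type batteries — the count depth
below which the simulations show surface estimates become unreliable.
Classification into the seven reporting categories allows
multi-membership, with "no significant ASE" exclusive.

## Surfaces and intervals

`predict_surface()` evaluates the fitted probability over a grid, masked
to points within a radius of observed spots (default twice the median
nearest-neighbour spacing) so surfaces keep the tissue's footprint; the
mask is a distance rule, not a concave hull. Pointwise variance is
delta-method through the coefficient covariance; intervals are formed on
the logit scale and mapped through the expit, so they are
order-preserving and stay inside $[0, 1]$. Intervals are pointwise, not
simultaneous, and labelled as such. For mixture fits the `"overall"`
surface weights per-cell-type expits by spot-averaged shares; requesting
a specific cell type takes that type's expit directly.
`cross_section()` profiles a surface along a segment,
arc-length-parameterized, for figures of the X-inactivation landscape
type; `merge_genes()` supports the high-coverage merged X-chromosome
profile (all X genes excluding *Xist*).

## The simulation framework

The generator emulates the features of real tissue that matter for
estimability while remaining fully synthetic:

- **Landscapes** (`sim_landscape()`): spots uniform on the unit square;
  cell-type weights from a softmax of random Gaussian bump fields
  ("blobs", the default — spatially clustered cell types of varying
  footprint), sharp vertical domains ("bands"), or exactly equal
  ("uniform").
- **Truth surfaces** (`sim_truth()`): logit-scale coefficients of the
  5-df basis drawn i.i.d. $N(0, 1.5^2)$ for the designated cell type,
  all other cell types flat at $p = 0.5$. The scale 1.5 was chosen once
  so that surfaces span roughly the 0.2–0.8 probability range seen in
  real tissue ASE maps; `coef_scale = 0` gives the global null.
- **Counts** (`sim_counts()`): the gene's total UMI is spread over spots
  by a multinomial proportional to $\sum_k w_{ik}\mu_{jk}$, then maternal
  counts drawn beta-binomially at the true surface ($\phi = 0$ draws
  exact binomials).
- **Evaluation** (`evaluate_fit()`): Pearson $r$ between fitted and true
  probabilities at the observed spots, and coefficient RMSE on the logit
  scale when the fitted layout matches the truth.

Per-replicate seeds are derived deterministically from a master seed, so
grids (`run_simulation_grid()`) are reproducible.

What the generator does *not* emulate: platform chemistry (Visium vs
Slide-seq enter only through spot density and counts per spot), upstream
deconvolution and rate-estimation error (weights and rates are taken as
known, as the model assumes), segmentation or registration artifacts, and
real spatial autocorrelation of cell-type fields beyond smooth bumps.
Passing simulations therefore validate the estimator and its calibration
under the model, not robustness to misspecified upstream inputs.

## Problem sizes and numerical choices

The test suite's simulation checks use sizes chosen to make the
statistical assertions sharp while keeping a full run desk-scale:
calibration of the spatial LRT uses 500 null replicates at 2,000 spots
and 5,000 UMI with $\phi = 0.1$ (the UMI depth and overdispersion are
mid-range values of the simulation design, fixed up front); FDR control
uses 200 genes with 10% strong effects; surface recovery uses 50
replicates per UMI bin over the bins 100–500, 500–1,000 and
1,000–10,000; interval calibration uses 20 replicates at 10,000 UMI.
Degenerate inputs are handled explicitly rather than by error: $\phi$
likelihoods flat in $\phi$ (every $n_i = 1$) are flagged, complete
separation is clipped and warned, zero-denominator mixture rows are
excluded, and boundary $\phi$ estimates are reported with a flag.

## Known limitations

- The within-cell-type spatial test inherits the identifiability of the
  mixture: cell types nearly absent from the slide (or below the share
  floor) cannot be tested.
- Wald intervals and tests rely on the observed information with $\phi$
  treated as fixed; for genes with very few informative spots the
  likelihood-ratio-based spatial tests are the more trustworthy pair of
  the suite.
- Serial-section registration is out of scope; inputs are assumed
  pre-registered, and coordinates are treated as arbitrary planar units.
- The cross-information between $\beta$ and $\phi$ is ignored in the
  covariance; simulations show interval coverage at nominal level under
  the model, but strong misspecification of the overdispersion could
  invalidate it.
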