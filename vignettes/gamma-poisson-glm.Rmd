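---
title: "Gamma-Poisson GLM inference for single-cell counts: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma-Poisson GLM inference for single-cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpglm)
```

## The model

Counts of a gene across comparable cells are modeled as
$y \sim \mathrm{GammaPoisson}(\mu, \theta)$: a Poisson draw whose rate is
itself Gamma-distributed with mean $\mu$ and shape $1/\theta$, giving
$\mathrm{Var}(Y) = \mu + \theta\mu^2$. We use the mean/overdispersion
parameterization ($\theta$ is the reciprocal of the classical negative
binomial *size*) because it makes $\theta = 0$ exactly the Poisson case —
the package evaluates that boundary with a dedicated Poisson branch rather
than as a numerical limit. Structure across cells enters through a
generalized linear model with a log link,
$\log \mu_{gc} = (X\beta_g)_c + \log s_c$, where the size factors $s_c$
absorb sequencing-depth differences as offsets. Counts are never divided by
size factors; they stay integers.

## Fitting one gene

**Coefficients.** For fixed $\theta$, $\hat\beta$ minimizes the deviance
$\sum_c d(y_c, \mu_c, \theta)$, where the unit deviance is twice the
log-likelihood gap to the saturated model, evaluated in its analytic limit
form so the $0\log 0$ terms at $y=0$ vanish exactly. The minimizer is found
by iteratively reweighted least squares with working weights
$w_c = \mu_c/(1+\theta\mu_c)$, solved through a rank-revealing QR
decomposition, with step-halving (up to 20 halvings) whenever a step would
increase the deviance — so the deviance is non-increasing across accepted
iterations. Convergence requires both a relative deviance change below
$10^{-11}$ and a vanishing score,
$\max_j |X^\top[(y-\mu)/(1+\theta\mu)]|_j \le 10^{-6}(1+|\sum y|)$. The
deviance criterion alone is not enough: it can plateau while coefficients
are still $10^{-3}$ away in relative terms, which breaks exact-invariance
properties downstream. The linear predictor is clamped to $[-30, 30]$; fits
ending on the clamp, or with $\lVert\beta\rVert_\infty > 50$, are flagged
rather than raised, and all-zero genes short-circuit to a flagged boundary
fit. Starting values come from least squares on $\log((y+0.5)/s)$.

**Overdispersion.** $\hat\theta$ maximizes the profile likelihood at the
current fitted means, optionally with the Cox–Reid adjustment
$-\tfrac12\log\det(X^\top W X)$ that corrects the bias from having estimated
$p$ coefficients. The adjustment is on by default: without it the estimator
is systematically low at small $n$ (the test suite checks this direction).
The search works on $\log\theta$ over $[10^{-8}, 10^6]$: a method-of-moments
start $\theta_0 = \max(0, \sum((y-\mu)^2-\mu)/\sum\mu^2)$, bracket
expansion, golden-section/parabolic refinement, then a bisection polish on
the *analytic* score $\partial\ell/\partial\log\theta$. The polish matters
for a subtle reason: any value-based 1-d search localizes a flat maximum
only to about $\sqrt{\varepsilon}$ relative precision, and the Cox–Reid
term differs between equivalent design parameterizations by an additive
constant, which perturbs value comparisons near the optimum. The score is
exactly invariant under reparameterization, so bisection on its sign makes
$\hat\theta$ (and everything downstream, e.g. the F statistics) agree to
$\sim 10^{-11}$ across design bases that span the same space. Solutions at
the lower boundary are reported as exactly 0.

**Bundling.** The likelihood (and its score) are evaluated over a bundled
representation of the per-gene data: observations are grouped by identical
count value and numerically identical fitted mean (relative tolerance
$10^{-10}$, i.e. only means that are equal up to floating-point noise are
merged — within the groups of a one-hot design, for example). Most entries
of a single-cell matrix are small integers, so the per-gene sum typically
collapses from *n* cells to a few dozen distinct pairs. This is an exact
reformulation, not an approximation; the tests assert bundled = dense at
$10^{-10}$ relative everywhere, and the representation falls back to dense
whenever fewer than half of the observations are repeats, so the worst case
costs the same as the naive sum.

**Alternation.** Coefficients and overdispersion are estimated by
alternating the two steps above from the moments start until
$|\Delta\log(\theta + 10^{-8})| < 10^{-4}$ (at most 10 outer rounds). Joint
alternation can in principle stall on a ridge; the test suite therefore
checks the attained joint likelihood against a derivative-free 2-d direct
search on small instances.

## The dispersion trend and the quasi-likelihood F-test

Gene-wise $\hat\theta$ are noisy at realistic cell numbers. A running-median
trend over $\log$ mean expression (centered window of $\max(11, 5\%)$ genes,
linearly interpolated between window centers, floored at $10^{-8}$) captures
the mean–dispersion relationship; with fewer than 10 usable genes the trend
degenerates to a constant with a warning.

Testing follows the quasi-likelihood construction: both the full and the
reduced model are refitted at the *trended* $\theta$, and the gene-wise
quasi-dispersion $\sigma^2_g = \mathrm{deviance}/\mathrm{df}$ absorbs the
residual gene-level departure from the trend. (Fitting at gene-wise
$\hat\theta$ instead is available via `use_trended_theta = FALSE`, but then
$\sigma^2$ no longer captures dispersion uncertainty.) The $\sigma^2_g$ are
shrunk toward a common location: writing $z_g = \log\sigma^2_g$ and assuming
$\sigma^2 \sim \sigma_0^2 F(d, d_0)$ with $d$ the residual df, moment
matching gives $\mathrm{Var}(z) = \psi'(d/2) + \psi'(d_0/2)$, so $d_0$
follows from the excess of the observed variance over $\psi'(d/2)$ by
trigamma inversion (Newton iteration), and $\sigma_0^2$ from the mean of $z$
with the matching digamma correction. Observed variance at or below the
theoretical minimum means no detectable gene-level variability and
$d_0 = \infty$; exactly constant $\sigma^2$ (a degenerate input the sampling
model cannot produce) returns the common value itself. The prior location is
global; a mean-dependent location was considered and not adopted — the
trended $\theta$ already removes the mean effect, and a second mean-dependent
layer would be confounded with it.

The test statistic is
$F = [(\mathrm{dev}_{\mathrm{red}} - \mathrm{dev}_{\mathrm{full}})/\mathrm{df}_1] / \sigma^2_{\mathrm{shrunk}}$
referred to $F(\mathrm{df}_1, d_0 + d)$, with the $\chi^2$ limit when
$d_0 = \infty$. Deviance-difference negatives within $10^{-8}$ are clipped
(floating-point guard); anything larger raises, because it indicates a
fitting bug rather than round-off. Benjamini–Hochberg adjustment and the
log2 fold change of a chosen contrast complete the per-gene table.

## Size factors and pseudobulk

The default size-factor estimator is the re-centered column sum
(`"normed-sum"`, geometric mean fixed at 1): in the many-zero single-cell
regime the median-of-ratios estimator is undefined for most genes.
Median-of-ratios is provided for bulk-like and pseudobulk matrices and falls
back to normed-sum (with a warning) when no gene has all-positive counts; it
requires the in-memory backend, because the per-cell median across all genes
cannot be computed exactly in a single gene-major pass. User-supplied
factors are accepted after a positivity check. Pseudobulk aggregation sums
counts exactly (integer arithmetic) over cells sharing a label, keeps
samples in first-appearance order, refuses covariates that vary within a
label, and re-estimates size factors on the aggregated matrix rather than
combining cell-level factors — the aggregated library sizes, not the cell
depths, are what matter for the sample-level model.

## Chunked and on-disk execution

Genes are conditionally independent given the design and size factors, so
fitting streams over contiguous gene blocks. Size factors come from a first
streaming pass over column sums. The on-disk backends re-read the source per
chunk (scanning MatrixMarket triplets, or walking the 10x CSC arrays in
column blocks via the `indptr` index), so at most `chunk_size × n_cells`
count values are resident. Backend and chunk size are a pure execution
choice: the tests assert gene-wise equality at $10^{-10}$ between in-memory
and on-disk runs at several chunk sizes, and the whole contract would be
meaningless if streaming changed results.

## What the simulations do and do not show

`simulate_counts()` draws from exactly the fitted model: Gamma rate then
Poisson draw (direct Poisson at $\theta = 0$), log-normal size factors
re-centered to geometric mean 1, per-gene seeds derived from one global seed
so gene order and subsetting never change any other gene's draws. Default
study conditions used across tests and the acceptance script, chosen once as
representative of a modest two-group single-cell comparison: base means
log-normal around 5 counts, overdispersion 0.3–0.4, size-factor log-sd 0.3,
200 cells in two balanced groups; dispersion recovery uses 300 genes × 500
cells at $\theta \in \{0.1, 0.5, 1\}$; the power-monotonicity check uses 40
cells so the power curve stays away from saturation and monotonicity is
resolvable. The fixture suite writes a two-group matrix with 10% non-null
genes at $|\mathrm{LFC}| = 1$ plus a matched null matrix, with ground-truth
tables.

Because the generator *is* the model, passing recovery and calibration tests
shows correctness of the inference machinery, not robustness to real data:
no doublets, ambient RNA, batch structure beyond design covariates,
zero-inflation beyond Gamma-Poisson sampling, or misspecified trends are
simulated.

## Known limitations

- The deviance-based quasi-dispersion is biased upward for discrete counts
  (its expectation exceeds 1 per df at moderate $\theta$ even under the true
  model), while the 1-df deviance drop in the numerator is asymptotically
  unbiased. The QL F-test is therefore mildly conservative at single-cell
  count sizes — observed type-I error around 0.04 at a nominal 0.05 under
  the null simulation. This is a property of the deviance/df construction
  itself, shared by classical quasi-likelihood pipelines, not a coding
  artifact; the acceptance checks measure it directly.
- Gene-wise $\theta$ MAP refitting (shrinking $\theta$ itself rather than
  the quasi-dispersion) is out of scope, as are ridge priors on $\beta$,
  LFC shrinkage, zero-inflated extensions and cell-level weights.
- `median-of-ratios` size factors need the matrix in memory (see above).
- HDF5 outputs are content-deterministic but not byte-deterministic (the
  format embeds write timestamps); all TSV/MatrixMarket outputs are
  byte-identical across reruns of identical inputs and seed.
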