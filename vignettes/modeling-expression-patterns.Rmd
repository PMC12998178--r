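---
title: "Spline models for temporal and spatial expression patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spline models for temporal and spatial expression patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splinegenes)
```

## The model and its assumptions

The package models a gene's library-size-normalized, log-transformed
expression as a smooth Gaussian-noise function of a one-dimensional axis
(pseudotime) or of two-dimensional tissue coordinates:

$$y_{ij} = \beta_{i0} + \sum_{k=1}^{K+3} b_k(t_j)\,\beta_{ik} +
\varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma_i^2),$$

with cubic B-spline bases $b_k$ on $K$ equidistant internal knots, and the
spatial analogue built from the tensor product of two per-axis bases
(intercept, $K+3$ marginal terms per axis, $(K+3)^2$ interactions;
$p = (K+4)^2$ columns in total). Three assumptions matter in practice:

1. **The axis is treated as fixed.** For measured spatial coordinates this
   is exact; for computationally inferred pseudotime it is optimistic, and
   the permutation mode below exists precisely to absorb that extra
   uncertainty.
2. **Gaussian errors on log expression.** Log-normalized single-cell data
   are zero-inflated and over-dispersed relative to a Gaussian; the
   least-squares fit is still a consistent estimate of the mean trend, but
   the exact F-test's finite-sample calibration is only as good as the
   normal approximation. Zero-inflated likelihoods would destroy the
   closed-form solution that makes the method fast, so they are out of
   scope.
3. **One trajectory branch at a time.** Multi-branch topologies are
   handled by running the model once per branch.

Because the design matrix depends only on the axis values, all genes share
one design and one hat matrix: the fitted matrix is
$\hat{\mathbf Y} = \mathbf Y \mathbf H$. `fit_genes()` factorizes the
design once (QR; column-pivoted SVD pseudoinverse if rank deficient) and
solves all genes as a multi-response system; the $n \times n$ hat matrix
itself is never formed. This is the entire efficiency story: fitting
thousands of genes costs one factorization plus one pass of
back-substitutions.

## Choosing the number of internal knots

`K = 0` (no internal knots, a single cubic segment) is the default and is
adequate for monotone or single-bump trends. The flexible mode selects $K$
per gene by the Gaussian BIC

$$n\log\!\Big(\tfrac1n\sum_j (y_{ij}-\hat y_{ij})^2\Big) + (K+5)\log n +
n + n\log 2\pi,$$

with the spatial penalty $(K+4)^2 + 1$ replacing $K+5$. Candidates default
to $0\ldots10$ (temporal) and $0\ldots5$ (spatial); infeasible candidates
(those with $n \le K+4$, resp. $n \le (K+4)^2$) are skipped with a
warning. Ties are broken toward the smaller $K$ — deterministic output and
parsimony. The residual mean square is floored at $10^{-12}$ inside the
logarithm so that a numerically perfect fit compares across $K$ through
the penalty term alone instead of producing $-\infty$.

Two conventions in the basis are choices, not consequences of the model,
and are worth stating. Boundary knots sit at the observed minimum and
maximum of each axis with multiplicity 4 (clamped cubic), which makes the
basis span constants and linears and makes fits invariant to axis-wise
affine rescaling (each axis of a spatial design gets its own knots from
its own range). And the full $K+4$-function basis is reduced to $K+3$
columns by dropping the first function, so that together with the explicit
intercept the design has full column rank while spanning the same space as
the partition-of-unity basis. Evaluation points outside the boundary
interval — possible only when a design is reused on new data — are clamped
to the boundary rather than rejected.

## Testing for variable genes

The null hypothesis is that all basis coefficients beyond the intercept
vanish (a flat curve/surface). The statistic is

$$F_i = \frac{\sum_j (\hat y_{ij} - \bar y_i)^2 / \mathrm{df}_1}
{\sum_j (y_{ij} - \hat y_{ij})^2 / \mathrm{df}_2},$$

with $(\mathrm{df}_1, \mathrm{df}_2) = (K+3,\; n-K-4)$ for curves and
$((K+4)^2-1,\; n-(K+4)^2)$ for surfaces. Under fixed axes and Gaussian
noise this is an exact F reference, used directly by `ftest_pvalues()` and
`svg_test()`. Degenerate inputs are made total rather than erroneous: a
gene whose fitted curve is indistinguishable from its mean (fitted
variance $\le 10^{-12}$, which covers constant genes) reports $F = 0$,
$p = 1$; a non-constant gene with residual variance $\le 10^{-12}$ reports
$F = \infty$, $p = 0$. Both stay in the BH adjustment — no silent drops.

### The permutation mode

When pseudotime is inferred, its sampling noise makes the exact test
anti-conservative. `permutation_test()` therefore repeats, $B = 100$
times: draw $\lfloor 0.8\,n \rfloor$ cells without replacement, obtain
pseudotime on the subsample (by default the restriction of the supplied
values; a callback hook lets users re-run their trajectory method per
replicate), permute it, and refit all genes — one shared design per
replicate, so the whole null ensemble costs $B$ ordinary fits. A Gamma
distribution is fitted per gene to its $B$ null F values by maximum
likelihood (`fitdistrplus`), and the p-value is the upper Gamma tail at
the observed full-data F; the Gamma smooths the far tail beyond the
$1/B$ resolution of a raw permutation p-value. Degenerate cases fall back
in order: method-of-moments, then the empirical tail $(\#\{F^{null}\ge
F\}+1)/(B+1)$, each with a logged warning.

Two decisions here were genuinely open. First, in the flexible-$K$ mode
the null refits reuse each gene's full-data $K$ rather than re-selecting
per replicate, keeping observed and null statistics on the same degrees of
freedom. Second, the observed F is compared against the null Gamma as-is
even though it was computed at the full $n$ while nulls use the subsample
$n$; the statistics are used raw, without df rescaling. Spatial testing
uses no permutation at all: coordinates are measured, not inferred.

All randomness flows from one user seed: replicate $r$ runs under its own
seed drawn up-front from the master stream, so any replicate can be
reproduced in isolation and runs are byte-identical given the seed.

## Binning

For datasets where even one fitted matrix is too large, `bin_temporal()`
averages expression within 100 equal-width pseudotime intervals and
`bin_spatial()` within an evenly spaced 100×100 grid, and the model is
then fitted to bin means at bin centers. Conventions: temporal intervals
are right-closed (first interval closed on both sides; the maximum belongs
to the last bin); spatial points exactly on an interior edge go to the
higher-index cell; empty bins are dropped, not imputed; bins are not
weighted by occupancy — the bin is the observational unit, and all df and
BIC formulas use the number of occupied bins. A prominent consequence:
p-values from binned runs are *not* comparable to unbinned p-values (the
effective sample size changes); rankings are the comparable quantity.

## The synthetic-data generators

`make_groundtruth()` produces the evaluation datasets: by default 2000
genes, 10% of which carry a smooth mean signal spanning
`effect_size * noise_sd = 1.5` units peak-to-trough (3 residual SDs with
the default `noise_sd = 0.5`, a typical per-gene SD of log-normalized
expression), additive Gaussian noise, pseudotime uniform on $[0,1]$ or
coordinates uniform on the unit square. Signal families — localized bump,
linear trend, and low-frequency sinusoid (temporal); Gaussian blob, linear
gradient, and oriented stripe (spatial) — are drawn per gene.
`resample_scaling_*()` reproduce the resampling construction used for
scalability experiments (columns drawn with replacement, integer
pseudotime $1..n$ or a full integer grid), and `make_null()` permutes the
axis for false-positive checks.

What the generator deliberately does **not** emulate: count-level
sampling, dropouts, gene–gene correlation, or mean–variance coupling. Its
noise is exactly the model's likelihood, so passing tests demonstrate the
correctness and calibration of the implementation under its own
assumptions — not robustness to real single-cell noise. One structural
consequence shows up in the consistency checks: 90% of the fixture's genes
are *exact* nulls, whose F-statistic ranks are pure noise and decorrelate
whenever the design changes. Rank-consistency measures across design
changes (rotated coordinates, binned vs unbinned) are therefore capped
well below 1 on these fixtures — we observe Spearman ≈ 0.85 under 45°
rotation and ≈ 0.8 for temporal binning — whereas on real tissues, where
nearly every gene has some structure, substantially higher agreement is
expected. The tensor-product basis itself also breaks rotational
symmetry, so exact invariance under rotation is impossible by
construction.

## Numerical choices and limitations

- $\hat\sigma_i^2$ is the $1/n$ residual-variance estimator throughout
  fitting, consistent with the BIC formula; the F statistic uses its own
  normalizations.
- Variance thresholds of $10^{-12}$ classify constant and perfect fits
  before ratios are formed (see above).
- Fitted values are computed per gene (matrix–vector products) rather than
  in one matrix–matrix product; optimized BLAS kernels otherwise give
  bit-different results depending on how many genes share a product, and
  per-gene products make block-wise fitting (`fit_genes_blocked()`, which
  bounds peak memory) bit-identical to the unblocked path.
- Dense text output writes 17 significant digits, enough for lossless
  double round trips.
- Result tables are sorted by ascending p-value with a stable tie-break on
  gene id, so downstream overlap/rank comparisons are deterministic.

Test and acceptance runs use deliberately moderate problem sizes — 2000
genes with 200–900 cells for calibration checks, 2000×500 power fixtures,
$B = 100$ permutation replicates — chosen so the entire suite exercises
every study-scale property in well under a minute each. Known
limitations: single-branch trajectories only; 2-D coordinates only; no
zero-inflated or count likelihoods; the exact F-test's p-values are only
approximate when pseudotime is inferred (use the permutation mode); very
fine-scale spatial features below the scale of the global fit are not
detectable from a single whole-tissue fit.
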