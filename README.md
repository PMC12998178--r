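# splinegenes

Fast spline-based modeling of temporal and spatial gene expression
patterns, and detection of temporally variable genes (TVGs) along a
pseudotime trajectory and spatially variable genes (SVGs) in spatial
transcriptomics data.

Single-cell RNA-seq pipelines infer a pseudotime ordering of cells along
continuous processes such as differentiation; spatial platforms (Visium,
Visium HD, HDST, Xenium, MERSCOPE) measure expression at 2-D tissue
coordinates. In both settings the analyst wants, for thousands of genes at
once, (i) a smooth fitted curve or surface of expression against the axis
and (ii) a calibrated test of whether the gene varies along it. Per-gene
smoothers (GAMs) repeat every design-matrix computation for every gene and
become infeasible for datasets with 10^5–10^6 cells. This package is for
analysts who need those fits and tests at that scale.

## Model

For gene *i* with expression *y<sub>ij</sub>* (library-size-normalized,
log-transformed) in cell *j* with pseudotime *t<sub>j</sub>*:

> y<sub>ij</sub> = β<sub>i0</sub> + Σ<sub>k=1..K+3</sub> b<sub>k</sub>(t<sub>j</sub>) β<sub>ik</sub> + ε<sub>ij</sub>,  ε<sub>ij</sub> ~ N(0, σ<sub>i</sub>²)

where b<sub>1</sub>…b<sub>K+3</sub> are cubic B-spline bases on *K*
equidistant internal knots. The design matrix **X** (and hence the hat
matrix **H** = **X**(**X**ᵀ**X**)⁻¹**X**ᵀ) depends only on the axis values,
so it is shared by all genes and the fitted matrix for the whole dataset is
the single product **Ŷ** = **Y H** — computed here via one QR factorization
and multi-response solves, never by materializing **H**. In the spatial
case the 1-D basis is replaced by the tensor product of two per-axis cubic
B-spline bases (intercept + marginals + interactions, p = (K+4)² columns).

*K* = 0 by default (fastest); alternatively *K* is selected per gene by the
Gaussian BIC `n log(RSS/n) + (K+5) log n + n + n log 2π` (spatial penalty
`(K+4)² + 1`), candidates 0–10 (temporal) or 0–5 (spatial).

TVGs/SVGs are identified either by the exact F-test —
F(K+3, n−K−4) for curves, F((K+4)²−1, n−(K+4)²) for surfaces, valid when
the axis is fixed — or, for inferred pseudotime, by a subsampling and
permutation procedure: 100 refits on permuted 80% subsamples give per-gene
null F statistics, a Gamma distribution is fitted to them by maximum
likelihood, and the p-value is the upper Gamma tail at the observed F.
All p-values are Benjamini–Hochberg adjusted.

## Worked example

```r
library(splinegenes)
sim <- make_groundtruth(n_genes = 300, n = 400, mode = "temporal", seed = 42)
fit <- fit_temporal(sim$Y, sim$axis, candidates = 0:10)   # per-gene K by BIC
res <- ftest_pvalues(fit, sim$Y)
print(fit)
head(res[order(res$pvalue), c("gene_id","K","F","df1","df2","pvalue","fdr")], 5)
```

```
gene_fit: 300 genes x 400 cells (temporal axis)
  K per gene: 0 -> 274, 1 -> 14, 2 -> 1, 3 -> 2, 4 -> 4, 5 -> 4, 6 -> 1
   gene_id K        F df1 df2       pvalue          fdr
 gene00006 1 132.4852   4 395 1.196582e-71 3.153348e-69
 gene00008 1 131.8238   4 395 2.102232e-71 3.153348e-69
 gene00005 1 126.9541   4 395 1.401483e-69 1.401483e-67
 gene00004 5  67.1098   8 391 1.063120e-68 7.973402e-67
 gene00015 1 117.7193   4 395 5.192046e-66 3.115228e-64
```

Most genes keep K = 0 (their trends are simple), while genes with wigglier
signals receive internal knots. `F` is the ratio of fitted-curve variation
to residual variation; at FDR ≤ 0.05 this run reports 33 of 300 genes as
temporally variable (30 are true positives by construction — the fixture
has a known 10% variable fraction). The permutation mode agrees closely:

```r
perm <- permutation_test(sim$Y, sim$axis, B = 100, seed = 42)
sum(perm$fdr <= 0.05)                                  # 31
cor(res$pvalue, perm$pvalue, method = "spearman")      # 0.95
```

Spatial data work the same way through `fit_spatial()` + `svg_test()`, with
spot coordinates instead of pseudotime. `bin_temporal()` / `bin_spatial()`
optionally average expression into 100 bins or a 100×100 grid first, for
very large datasets. A command-line front end is installed at
`system.file("cli", "splinegenes.R", package = "splinegenes")` with
subcommands `fit-temporal`, `test-tvg`, `fit-spatial`, `test-svg` and
`simulate`.

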