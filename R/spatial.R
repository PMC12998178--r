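# Tensor-product surface fitting and the exact F-test for spatially
# variable genes.

#' Per-gene knot selection by BIC (spatial)
#'
#' As [select_K()] but with the tensor-product design and the spatial BIC
#' penalty `(K + 4)^2 + 1`. Candidates for which `n <= (K + 4)^2` are
#' skipped with a warning; if no candidate is feasible an error is raised.
#'
#' @param Y Genes x spots expression matrix.
#' @param S `n x 2` matrix of spot coordinates aligned to the columns of
#'   `Y`.
#' @param candidates Integer candidate set (default 0..5).
#' @param n_blocks Gene blocking passed to [fit_genes()].
#' @return As [select_K()].
#' @export
select_K_spatial <- function(Y, S, candidates = 0:5, n_blocks = 1L) {
  select_K_engine(
    Y, candidates,
    design_fun = function(K) spatial_design(S, K),
    penalty_fun = function(K) (K + 4)^2 + 1,
    feasible = function(K, n) n > (K + 4)^2,
    n_blocks = n_blocks
  )
}

#' Fit spatial expression surfaces for all genes
#'
#' Fits a smooth surface over 2-D coordinates per gene with the
#' tensor-product cubic B-spline design, sharing one design factorization
#' across all genes. With `candidates` supplied, each gene's `K` is chosen
#' by BIC (spatial penalty) and genes are refitted grouped by selected `K`.
#'
#' @param Y Genes x spots expression matrix.
#' @param S `n x 2` coordinate matrix aligned to the columns of `Y`.
#' @param K Fixed number of internal knots per axis (ignored when
#'   `candidates` is given).
#' @param candidates Optional candidate set for per-gene BIC selection
#'   (default used when `NULL` is 0..5 at the CLI level).
#' @param n_blocks Gene blocking passed to [fit_genes()].
#' @return A `"gene_fit"` object; see [fit_genes()].
#' @export
fit_spatial <- function(Y, S, K = 0L, candidates = NULL, n_blocks = 1L) {
  Y <- as.matrix(Y)
  S <- as.matrix(S)
  if (ncol(Y) != nrow(S))
    stop("nrow(S) must equal ncol(Y)")
  if (is.null(candidates)) {
    if (ncol(Y) <= (K + 4)^2)
      warning("n <= (K + 4)^2: surface fit is saturated and the exact test ",
              "is undefined")
    return(fit_genes(Y, spatial_design(S, K), n_blocks = n_blocks))
  }
  sel <- select_K_spatial(Y, S, candidates, n_blocks = n_blocks)
  fit <- fit_by_gene_K(Y, sel$selected,
                       function(K) spatial_design(S, K),
                       n_blocks = n_blocks)
  fit$bic <- sel$bic
  fit
}

#' Exact F-test for spatially variable genes
#'
#' Tests, per gene, whether all marginal and interaction surface
#' coefficients are zero. Because spatial locations are measured rather
#' than inferred, the exact `F((K + 4)^2 - 1, n - (K + 4)^2)` reference
#' applies directly and no subsampling or permutation is used. Upper-tail
#' p-values are BH-adjusted across genes.
#'
#' @param fit A spatial `"gene_fit"` from [fit_spatial()].
#' @param Y The expression matrix the fit was computed from.
#' @return A data.frame with columns `gene_id, K, F, df1, df2, pvalue,
#'   fdr`, in input gene order.
#' @export
svg_test <- function(fit, Y) {
  if (fit$axis_kind != "spatial")
    stop("'fit' is not a spatial fit; use ftest_pvalues() for temporal fits")
  res <- f_table(fit, Y)
  res$pvalue <- stats::pf(res$F, res$df1, res$df2, lower.tail = FALSE)
  res$fdr <- bh_adjust(res$pvalue)
  res
}
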