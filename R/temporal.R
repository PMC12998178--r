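# Temporal fitting, BIC knot selection, exact F-test and the
# subsample-permutation test with Gamma tail calibration.

# Gaussian-likelihood BIC from a per-gene residual mean square. The mean
# square is floored at 1e-12 before the log so a perfect fit never yields
# -Inf; the floor preserves the ordering across K because the penalty term
# still differs.
bic_from_rms <- function(rms, penalty_df, n) {
  n * log(pmax(rms, 1e-12)) + penalty_df * log(n) + n + n * log(2 * pi)
}

#' BIC of a temporal spline fit for one gene
#'
#' `n * log(rss / n) + (K + 5) * log(n) + n + n * log(2 * pi)`, the Gaussian
#' BIC with `K + 5` parameters (intercept, `K + 3` basis coefficients and
#' the residual variance). The residual mean square is floored at `1e-12`.
#'
#' @param y,yhat Observed and fitted expression of one gene.
#' @param K Number of internal knots used in the fit.
#' @param n Number of cells (defaults to `length(y)`).
#' @return The BIC value (finite).
#' @export
bic_temporal <- function(y, yhat, K, n = length(y)) {
  if (length(y) != length(yhat))
    stop("'y' and 'yhat' must have equal length")
  bic_from_rms(mean((y - yhat)^2), K + 5, n)
}

#' BIC of a spatial tensor-product fit for one gene
#'
#' As [bic_temporal()] but with `(K + 4)^2 + 1` parameters: the
#' `(K + 4)^2` surface coefficients plus the residual variance.
#'
#' @inheritParams bic_temporal
#' @return The BIC value.
#' @export
bic_spatial <- function(y, yhat, K, n = length(y)) {
  if (length(y) != length(yhat))
    stop("'y' and 'yhat' must have equal length")
  bic_from_rms(mean((y - yhat)^2), (K + 4)^2 + 1, n)
}

# Shared BIC scan over candidate K values. `design_fun(K)` builds the
# design, `penalty_fun(K)` gives the BIC parameter count, `feasible(K, n)`
# says whether the exact test/fit is well defined at that K.
select_K_engine <- function(Y, candidates, design_fun, penalty_fun, feasible,
                            n_blocks = 1L) {
  Y <- as.matrix(Y)
  n <- ncol(Y)
  candidates <- sort(unique(as.integer(candidates)))
  if (!length(candidates)) stop("empty candidate set")
  feas <- candidates[vapply(candidates, feasible, logical(1), n = n)]
  if (length(feas) < length(candidates))
    warning("skipping infeasible candidate K = ",
            paste(setdiff(candidates, feas), collapse = ", "),
            " (too few observations)")
  if (!length(feas)) stop("no feasible candidate K for n = ", n)
  bic <- matrix(NA_real_, nrow(Y), length(feas),
                dimnames = list(rownames(Y), as.character(feas)))
  for (ci in seq_along(feas)) {
    K <- feas[ci]
    f <- fit_genes(Y, design_fun(K), n_blocks = n_blocks)
    bic[, ci] <- bic_from_rms(rowMeans((Y - f$Yhat)^2), penalty_fun(K), n)
  }
  # argmin with ties broken toward smaller K (feas is sorted increasing)
  selected <- feas[max.col(-bic, ties.method = "first")]
  list(selected = stats::setNames(selected, rownames(Y)), bic = bic,
       candidates = feas)
}

#' Per-gene knot selection by BIC (temporal)
#'
#' For each candidate `K` one shared design and one fitted matrix are
#' computed for all genes at once; each gene then gets the `K` minimizing
#' its BIC, with ties broken toward the smaller `K`. Candidates for which
#' `n <= K + 4` are skipped with a warning.
#'
#' @param Y Genes x cells expression matrix.
#' @param t Per-cell pseudotime values aligned to the columns of `Y`.
#' @param candidates Integer set of candidate knot counts (default 0..10).
#' @param n_blocks Gene blocking passed to [fit_genes()].
#'
#' @return A list with `selected` (named integer vector, one K per gene),
#'   `bic` (genes x candidates matrix) and `candidates` (the feasible set).
#' @export
select_K <- function(Y, t, candidates = 0:10, n_blocks = 1L) {
  select_K_engine(
    Y, candidates,
    design_fun = function(K) temporal_design(t, K),
    penalty_fun = function(K) K + 5,
    feasible = function(K, n) n > K + 4,
    n_blocks = n_blocks
  )
}

#' Fit temporal expression curves for all genes
#'
#' The main temporal fitting entry point. With a fixed `K` (default 0, the
#' fastest setting) all genes share one design; with `candidates` supplied,
#' each gene's `K` is chosen by BIC via [select_K()] and genes are refitted
#' grouped by their selected `K`, still one shared factorization per
#' distinct `K`.
#'
#' @param Y Genes x cells expression matrix.
#' @param t Per-cell pseudotime values aligned to the columns of `Y`.
#' @param K Fixed number of internal knots (ignored when `candidates` is
#'   given).
#' @param candidates Optional candidate set for per-gene BIC selection.
#' @param n_blocks Gene blocking passed to [fit_genes()].
#' @return A `"gene_fit"` object; see [fit_genes()].
#' @export
fit_temporal <- function(Y, t, K = 0L, candidates = NULL, n_blocks = 1L) {
  Y <- as.matrix(Y)
  if (ncol(Y) != length(t))
    stop("length of 't' must equal ncol(Y)")
  if (is.null(candidates))
    return(fit_genes(Y, temporal_design(t, K), n_blocks = n_blocks))
  sel <- select_K(Y, t, candidates, n_blocks = n_blocks)
  fit <- fit_by_gene_K(Y, sel$selected,
                       function(K) temporal_design(t, K),
                       n_blocks = n_blocks)
  fit$bic <- sel$bic
  fit
}

#' F statistic of one temporal fit
#'
#' `F = [sum (yhat - ybar)^2 / (K + 3)] / [sum (y - yhat)^2 / (n - K - 4)]`.
#' A constant gene (fitted curve indistinguishable from its mean) yields
#' `F = 0`; zero residuals with a non-constant fit yield `F = Inf`.
#'
#' @inheritParams bic_temporal
#' @return A list with `F`, `df1 = K + 3` and `df2 = n - K - 4`.
#' @export
f_statistic <- function(y, yhat, K, n = length(y)) {
  if (n <= K + 4)
    stop("F statistic requires n > K + 4")
  df1 <- K + 3
  df2 <- n - K - 4
  f <- f_stats_vec(matrix(y, nrow = 1), matrix(yhat, nrow = 1), df1, df2)
  list(F = f, df1 = df1, df2 = df2)
}

# Vectorized F statistics over gene rows. Variance thresholds at 1e-12
# (on the 1/n scale) classify constant fits (F = 0) and perfect fits
# (F = Inf) before the ratio is formed.
f_stats_vec <- function(Y, Yhat, df1, df2) {
  n <- ncol(Y)
  num <- rowSums((Yhat - rowMeans(Y))^2)
  den <- rowSums((Y - Yhat)^2)
  const_fit <- num / n <= 1e-12
  perfect <- den / n <= 1e-12
  f <- numeric(nrow(Y))
  f[const_fit] <- 0
  f[!const_fit & perfect] <- Inf
  ok <- !const_fit & !perfect
  f[ok] <- (num[ok] / df1[if (length(df1) > 1) ok else 1]) /
    (den[ok] / df2[if (length(df2) > 1) ok else 1])
  f
}

# Assemble the per-gene F table for a fit; df convention depends on the
# axis kind: (K+3, n-K-4) temporal, ((K+4)^2 - 1, n - (K+4)^2) spatial.
f_table <- function(fit, Y) {
  Y <- as.matrix(Y)
  stopifnot(inherits(fit, "gene_fit"),
            identical(dim(Y), dim(fit$Yhat)))
  n <- fit$n
  K <- as.numeric(fit$K_per_gene)
  if (fit$axis_kind == "temporal") {
    df1 <- K + 3
    df2 <- n - K - 4
  } else {
    df1 <- (K + 4)^2 - 1
    df2 <- n - (K + 4)^2
  }
  if (any(df2 <= 0))
    stop("exact test undefined: n too small for the fitted K")
  f <- f_stats_vec(Y, fit$Yhat, df1, df2)
  data.frame(
    gene_id = if (is.null(rownames(Y))) paste0("gene", seq_len(nrow(Y)))
              else rownames(Y),
    K = as.integer(K), F = f, df1 = as.integer(df1), df2 = as.integer(df2),
    stringsAsFactors = FALSE
  )
}

#' Exact F-test p-values for temporally variable genes
#'
#' Upper-tail p-values of the exact `F(K + 3, n - K - 4)` reference
#' distribution (valid under fixed pseudotime), BH-adjusted across genes.
#' `F = 0` maps to `p = 1` and `F = Inf` to `p = 0`.
#'
#' @param fit A temporal `"gene_fit"`.
#' @param Y The expression matrix the fit was computed from.
#' @return A data.frame with columns `gene_id, K, F, df1, df2, pvalue,
#'   fdr, mode`, in input gene order.
#' @export
ftest_pvalues <- function(fit, Y) {
  if (fit$axis_kind != "temporal")
    stop("'fit' is not a temporal fit; use svg_test() for spatial fits")
  res <- f_table(fit, Y)
  res$pvalue <- stats::pf(res$F, res$df1, res$df2, lower.tail = FALSE)
  res$fdr <- bh_adjust(res$pvalue)
  res$mode <- "ftest"
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjusted p-values (capped at 1), via
#' [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

# Gamma upper-tail p-value for one gene's observed F against its B null
# F values. Primary route: maximum likelihood (fitdistrplus); fallback:
# method of moments; last resort: the empirical tail (count+1)/(B+1).
gamma_tail_pvalue <- function(f_obs, null_f) {
  nf <- null_f[is.finite(null_f) & null_f > 0]
  par <- NULL
  fallback <- "mle"
  if (length(nf) >= 2 && stats::var(nf) > 0) {
    par <- tryCatch(
      as.list(fitdistrplus::fitdist(nf, "gamma", method = "mle")$estimate),
      error = function(e) NULL
    )
    if (is.null(par)) {
      mu <- mean(nf)
      v <- stats::var(nf)
      if (is.finite(mu) && is.finite(v) && v > 0) {
        par <- list(shape = mu^2 / v, rate = mu / v)
        fallback <- "moments"
      }
    }
  }
  if (is.null(par) || !all(is.finite(unlist(par))) || par$shape <= 0 ||
      par$rate <= 0) {
    B <- sum(is.finite(null_f))
    return(list(
      pvalue = (sum(null_f >= f_obs, na.rm = TRUE) + 1) / (B + 1),
      shape = NA_real_, rate = NA_real_, fallback = "empirical"
    ))
  }
  list(pvalue = stats::pgamma(f_obs, shape = par$shape, rate = par$rate,
                              lower.tail = FALSE),
       shape = par$shape, rate = par$rate, fallback = fallback)
}

#' Permutation test for temporally variable genes with Gamma calibration
#'
#' Accounts for the uncertainty of computationally inferred pseudotime. In
#' each of `B` replicates, `floor(subsample_frac * n)` cells are drawn
#' without replacement, pseudotime on the subsample is obtained from
#' `infer` (default: the restriction of the supplied `t`), randomly
#' permuted, and all genes are refitted on the subsample with one shared
#' design per replicate, yielding one null F per gene per replicate. A
#' Gamma distribution is fitted per gene to its `B` null F values by
#' maximum likelihood (method-of-moments, then the empirical tail, as
#' fallbacks for degenerate cases) and the p-value is the upper Gamma tail
#' at the observed full-data F. BH is applied across genes.
#'
#' All randomness derives from `seed`: replicate `r` runs under its own
#' seed drawn up-front, so any single replicate is reproducible in
#' isolation.
#'
#' @inheritParams fit_temporal
#' @param B Number of subsample-permutation replicates (default 100).
#' @param subsample_frac Fraction of cells kept per replicate (default 0.8).
#' @param infer Optional callback `function(Y_sub, t_sub)` returning
#'   pseudotime for the subsampled cells, for users who wish to re-run
#'   trajectory inference per replicate; the default reuses the supplied
#'   pseudotime restricted to the subsample.
#' @param seed Integer seed governing all randomness.
#' @return A data.frame as [ftest_pvalues()] with `mode = "permutation"`,
#'   plus attributes `null_gamma` (genes x 2 matrix of fitted shape/rate)
#'   and `null_F` (genes x B matrix of null statistics).
#' @export
permutation_test <- function(Y, t, K = 0L, candidates = NULL, B = 100L,
                             subsample_frac = 0.8, infer = NULL, seed = 1L,
                             n_blocks = 1L) {
  if (B < 2) stop("'B' must be at least 2")
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("'subsample_frac' must be in (0, 1]")
  Y <- as.matrix(Y)
  n <- ncol(Y)
  m <- nrow(Y)
  full <- fit_temporal(Y, t, K = K, candidates = candidates,
                       n_blocks = n_blocks)
  obs <- f_table(full, Y)
  Kg <- as.integer(full$K_per_gene)

  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, B)
  n_sub <- floor(subsample_frac * n)
  if (n_sub <= max(Kg) + 4)
    stop("subsample too small for the fitted K: floor(subsample_frac * n) = ",
         n_sub)
  null_F <- matrix(NA_real_, m, B, dimnames = list(rownames(Y), NULL))
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n_sub)
    Ysub <- Y[, idx, drop = FALSE]
    tsub <- if (is.null(infer)) t[idx] else infer(Ysub, t[idx])
    tperm <- sample(tsub)
    # null fits reuse each gene's full-data K (fixed df between observed
    # and null statistics)
    fsub <- fit_by_gene_K(Ysub, Kg, function(K) temporal_design(tperm, K),
                          n_blocks = n_blocks)
    null_F[, b] <- f_stats_vec(Ysub, fsub$Yhat, Kg + 3, n_sub - Kg - 4)
  }

  shape <- rate <- rep(NA_real_, m)
  pval <- numeric(m)
  n_fallback <- 0L
  for (i in seq_len(m)) {
    g <- gamma_tail_pvalue(obs$F[i], null_F[i, ])
    pval[i] <- g$pvalue
    shape[i] <- g$shape
    rate[i] <- g$rate
    if (g$fallback != "mle") n_fallback <- n_fallback + 1L
  }
  if (n_fallback > 0)
    warning(n_fallback,
            " gene(s) used a method-of-moments or empirical-tail fallback ",
            "for the Gamma null")
  res <- obs
  res$pvalue <- pval
  res$fdr <- bh_adjust(pval)
  res$mode <- "permutation"
  attr(res, "null_gamma") <- cbind(shape = shape, rate = rate)
  attr(res, "null_F") <- null_F
  res
}
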