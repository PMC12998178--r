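# Multi-gene least squares with one shared design factorization.

#' Fit all genes against one shared spline design
#'
#' Solves the least-squares problem for every gene (row of `Y`) against the
#' same design matrix, factorizing the design exactly once. The fitted
#' matrix equals `Y %*% H` with `H = X (X'X)^{-1} X'`, but the hat matrix is
#' never materialized: coefficients for all genes are obtained from a single
#' QR factorization and fitted values as `X %*% coef`. Rank-deficient
#' designs fall back to the minimum-norm pseudoinverse solution with a
#' warning.
#'
#' @param Y Numeric genes x cells matrix (library-size-normalized,
#'   log-transformed expression), rows named by gene and columns by cell.
#' @param design A [temporal_design()] or [spatial_design()] whose rows
#'   align with the columns of `Y`.
#' @param n_blocks Number of gene blocks processed sequentially; the result
#'   is identical for any value, but peak intermediate storage scales with
#'   `nrow(Y) / n_blocks`.
#'
#' @return An object of class `"gene_fit"`: list with `Yhat` (fitted
#'   matrix), `beta` (genes x p coefficients), `sigma2` (per-gene residual
#'   variance, the `1/n` estimator), `K_per_gene`, `n`, `axis_kind` and
#'   `designs` (designs keyed by K as character).
#'
#' @examples
#' t <- seq(0, 1, length.out = 50)
#' Y <- rbind(g1 = 2 + 3 * t, g2 = rep(1, 50))
#' f <- fit_genes(Y, temporal_design(t, K = 0))
#' max(abs(f$Yhat - Y)) # both rows lie in the spline space
#' @export
fit_genes <- function(Y, design, n_blocks = 1L) {
  Y <- as.matrix(Y)
  if (!inherits(design, "spline_design"))
    stop("'design' must be a spline_design")
  X <- design$X
  if (ncol(Y) != nrow(X))
    stop("dimension mismatch: Y has ", ncol(Y), " columns but the design has ",
         nrow(X), " rows")
  if (!all(is.finite(Y)))
    stop("expression matrix must be finite (missing values are not supported)")
  m <- nrow(Y)
  n <- ncol(Y)
  p <- ncol(X)
  qrX <- qr(X)
  rank_def <- qrX$rank < p
  if (rank_def) {
    warning("rank-deficient design (rank ", qrX$rank, " < ", p,
            "); using the minimum-norm pseudoinverse solution")
    sv <- svd(X)
    keep <- sv$d > max(sv$d) * 1e-10
    U <- sv$u[, keep, drop = FALSE]
    V <- sv$v[, keep, drop = FALSE]
    d <- sv$d[keep]
  }
  n_blocks <- max(1L, as.integer(n_blocks))
  block_size <- ceiling(m / min(n_blocks, m))
  block_of <- ceiling(seq_len(m) / block_size)
  beta <- matrix(NA_real_, m, p, dimnames = list(rownames(Y), colnames(X)))
  Yhat <- matrix(NA_real_, m, n, dimnames = dimnames(Y))
  for (b in unique(block_of)) {
    idx <- which(block_of == b)
    Yt <- t(Y[idx, , drop = FALSE])
    bt <- matrix(NA_real_, p, length(idx))
    if (rank_def) {
      # per-gene solves/products keep results independent of block layout
      for (j in seq_along(idx))
        bt[, j] <- V %*% (crossprod(U, Yt[, j]) / d)
    } else {
      bt[] <- qr.coef(qrX, Yt)
    }
    beta[idx, ] <- t(bt)
    for (j in seq_along(idx))
      Yhat[idx[j], ] <- X %*% bt[, j]
  }
  sigma2 <- rowMeans((Y - Yhat)^2)
  K <- design$knots[[1]]$K
  structure(
    list(Yhat = Yhat, beta = beta, sigma2 = sigma2,
         K_per_gene = stats::setNames(rep.int(K, m), rownames(Y)),
         n = n, axis_kind = design$axis_kind,
         designs = stats::setNames(list(design), as.character(K))),
    class = "gene_fit"
  )
}

#' Block-wise gene fitting with bounded memory
#'
#' Identical output to [fit_genes()]; genes are processed in `n_blocks`
#' bins against the same design factorization so that intermediate storage
#' is proportional to `(nrow(Y) / n_blocks) * ncol(Y)`. Useful when the
#' fitted matrix of all genes at once would not fit in memory.
#'
#' @inheritParams fit_genes
#' @return See [fit_genes()].
#' @export
fit_genes_blocked <- function(Y, design, n_blocks = 10L) {
  fit_genes(Y, design, n_blocks = n_blocks)
}

# Fit genes where each gene carries its own K: groups genes by K, builds one
# design per distinct K (via `design_fun(K)`), fits each group with the
# shared factorization, and reassembles results in input gene order.
fit_by_gene_K <- function(Y, K_per_gene, design_fun, n_blocks = 1L) {
  Y <- as.matrix(Y)
  m <- nrow(Y)
  n <- ncol(Y)
  Ks <- sort(unique(K_per_gene))
  p_max <- 0L
  designs <- list()
  Yhat <- matrix(NA_real_, m, n, dimnames = dimnames(Y))
  sigma2 <- numeric(m)
  beta_list <- vector("list", length(Ks))
  idx_list <- vector("list", length(Ks))
  for (i in seq_along(Ks)) {
    K <- Ks[i]
    d <- design_fun(K)
    designs[[as.character(K)]] <- d
    idx <- which(K_per_gene == K)
    f <- fit_genes(Y[idx, , drop = FALSE], d, n_blocks = n_blocks)
    Yhat[idx, ] <- f$Yhat
    sigma2[idx] <- f$sigma2
    beta_list[[i]] <- f$beta
    idx_list[[i]] <- idx
    p_max <- max(p_max, ncol(f$beta))
  }
  beta <- matrix(NA_real_, m, p_max, dimnames = list(rownames(Y), NULL))
  for (i in seq_along(Ks))
    beta[idx_list[[i]], seq_len(ncol(beta_list[[i]]))] <- beta_list[[i]]
  axis_kind <- designs[[1]]$axis_kind
  structure(
    list(Yhat = Yhat, beta = beta, sigma2 = stats::setNames(sigma2, rownames(Y)),
         K_per_gene = stats::setNames(K_per_gene, rownames(Y)),
         n = n, axis_kind = axis_kind, designs = designs),
    class = "gene_fit"
  )
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("gene_fit:", nrow(x$Yhat), "genes x", x$n,
      if (x$axis_kind == "temporal") "cells" else "spots",
      sprintf("(%s axis)\n", x$axis_kind))
  cat("  K per gene:", paste(names(table(x$K_per_gene)), "->",
                             as.integer(table(x$K_per_gene)),
                             collapse = ", "), "\n")
  invisible(x)
}
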