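# Synthetic-data generators: resampling-based scalability datasets,
# ground-truth variable-gene datasets, permuted-axis null datasets, and the
# ranking-comparison metrics used to evaluate them. All generators are pure
# functions of their inputs and a seed.

#' Resampled scalability dataset with integer pseudotime
#'
#' Samples `n_target` cells with replacement from a base expression matrix
#' (expression profiles are carried over unchanged) and assigns pseudotime
#' as the consecutive integers `1..n_target`.
#'
#' @param base Genes x cells expression matrix to resample from.
#' @param n_target Number of cells in the resampled dataset (>= 2).
#' @param seed Integer seed.
#' @return A list with `Y` (genes x `n_target`) and `t` (named integer
#'   pseudotime `1..n_target`).
#' @export
resample_scaling_temporal <- function(base, n_target, seed) {
  base <- as.matrix(base)
  if (ncol(base) < 1) stop("'base' is empty")
  if (n_target < 2) stop("'n_target' must be at least 2")
  set.seed(as.integer(seed))
  idx <- sample.int(ncol(base), n_target, replace = TRUE)
  Y <- base[, idx, drop = FALSE]
  colnames(Y) <- paste0("cell", seq_len(n_target))
  t <- stats::setNames(as.numeric(seq_len(n_target)), colnames(Y))
  list(Y = Y, t = t)
}

#' Resampled scalability dataset on a full integer grid
#'
#' Samples `prod(grid)` spots with replacement from a base matrix and
#' assigns spatial locations as all combinations of the consecutive
#' integers `1..grid[1]` and `1..grid[2]`.
#'
#' @param base Genes x spots expression matrix to resample from.
#' @param grid Integer pair `(i, j)`; the dataset has `i * j` spots.
#' @param seed Integer seed.
#' @return A list with `Y` and `S` (spots x 2 integer coordinates).
#' @export
resample_scaling_spatial <- function(base, grid, seed) {
  base <- as.matrix(base)
  grid <- as.integer(grid)
  if (length(grid) != 2 || any(grid < 1)) stop("'grid' must be two integers >= 1")
  n <- grid[1] * grid[2]
  set.seed(as.integer(seed))
  idx <- sample.int(ncol(base), n, replace = TRUE)
  Y <- base[, idx, drop = FALSE]
  colnames(Y) <- paste0("spot", seq_len(n))
  S <- cbind(rep(seq_len(grid[1]), each = grid[2]),
             rep(seq_len(grid[2]), times = grid[1]))
  storage.mode(S) <- "double"
  rownames(S) <- colnames(Y)
  colnames(S) <- c("x", "y")
  list(Y = Y, S = S)
}

# Rescale a raw signal shape to span exactly `amp` units peak-to-trough,
# with a random sign.
scale_signal <- function(g, amp, sign) {
  rng <- max(g) - min(g)
  if (rng == 0) return(rep(0, length(g)))
  sign * (g - min(g)) / rng * amp
}

temporal_signal <- function(family, t) {
  switch(family,
    "spline-bump" = {
      ctr <- stats::runif(1, 0.2, 0.8)
      wid <- stats::runif(1, 0.05, 0.15)
      exp(-(t - ctr)^2 / (2 * wid^2))
    },
    "linear" = t,
    "sinusoid" = {
      f <- sample(1:2, 1)
      ph <- stats::runif(1, 0, 2 * pi)
      sin(2 * pi * f * t + ph)
    },
    stop("unknown temporal signal family: ", family)
  )
}

spatial_signal <- function(family, S) {
  switch(family,
    "gaussian-blob" = {
      ctr <- stats::runif(2, 0.2, 0.8)
      wid <- stats::runif(1, 0.1, 0.2)
      exp(-((S[, 1] - ctr[1])^2 + (S[, 2] - ctr[2])^2) / (2 * wid^2))
    },
    "gradient" = {
      th <- stats::runif(1, 0, 2 * pi)
      cos(th) * S[, 1] + sin(th) * S[, 2]
    },
    "stripe" = {
      th <- stats::runif(1, 0, 2 * pi)
      f <- stats::runif(1, 0.8, 1.5)
      ph <- stats::runif(1, 0, 2 * pi)
      sin(2 * pi * f * (cos(th) * S[, 1] + sin(th) * S[, 2]) + ph)
    },
    stop("unknown spatial signal family: ", family)
  )
}

#' Ground-truth dataset with a known fraction of variable genes
#'
#' Generates a Gaussian mean-plus-noise expression matrix in which a stated
#' fraction of genes carries a smooth mean signal along the axis (the
#' remainder have constant means), together with the truth labels needed
#' for precision-recall evaluation. Variable genes draw a signal family at
#' random (temporal: localized bump, linear trend, sinusoid; spatial:
#' Gaussian blob, linear gradient, oriented stripe) scaled to span
#' `effect_size * noise_sd` units peak-to-trough.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n Number of cells or spots (default 500).
#' @param mode `"temporal"` (pseudotime uniform on `[0, 1]`) or
#'   `"spatial"` (coordinates uniform on the unit square).
#' @param fraction_variable Fraction of genes with a true signal (default
#'   0.10; exactly `round(fraction_variable * n_genes)` genes are labeled
#'   `TRUE`).
#' @param effect_size Signal amplitude in residual-SD units (default 3).
#' @param noise_sd Residual standard deviation of the additive Gaussian
#'   noise (default 0.5, a typical per-gene SD of log-normalized
#'   expression).
#' @param signal_family Optional single family name to use for all
#'   variable genes; by default each variable gene samples one at random.
#' @param seed Integer seed.
#'
#' @return A list with `Y` (genes x n), `axis` (named pseudotime vector or
#'   coordinate matrix with spot rownames) and `truth` (logical per gene,
#'   `TRUE` for genes with a real signal).
#' @export
make_groundtruth <- function(n_genes = 2000L, n = 500L,
                             mode = c("temporal", "spatial"),
                             fraction_variable = 0.10, effect_size = 3,
                             noise_sd = 0.5, signal_family = NULL,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (fraction_variable < 0 || fraction_variable > 1)
    stop("'fraction_variable' must be in [0, 1]")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  set.seed(as.integer(seed))
  id_prefix <- if (mode == "temporal") "cell" else "spot"
  ids <- paste0(id_prefix, seq_len(n))
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  if (mode == "temporal") {
    axis <- stats::setNames(stats::runif(n), ids)
    pts <- axis
  } else {
    axis <- cbind(x = stats::runif(n), y = stats::runif(n))
    rownames(axis) <- ids
    pts <- axis
  }
  n_var <- round(fraction_variable * n_genes)
  truth <- c(rep(TRUE, n_var), rep(FALSE, n_genes - n_var))
  families <- if (mode == "temporal") c("spline-bump", "linear", "sinusoid")
              else c("gaussian-blob", "gradient", "stripe")
  if (!is.null(signal_family)) {
    if (!signal_family %in% families)
      stop("'signal_family' must be one of: ", paste(families, collapse = ", "))
    families <- signal_family
  }
  amp <- effect_size * noise_sd
  M <- matrix(0, n_genes, n)
  baseline <- stats::runif(n_genes, 0.2, 2)
  for (i in seq_len(n_var)) {
    fam <- if (length(families) == 1) families else sample(families, 1)
    g <- if (mode == "temporal") temporal_signal(fam, pts)
         else spatial_signal(fam, pts)
    M[i, ] <- scale_signal(g, amp, sample(c(-1, 1), 1))
  }
  Y <- M + baseline +
    matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n)
  dimnames(Y) <- list(gene_ids, ids)
  list(Y = Y, axis = axis, truth = stats::setNames(truth, gene_ids))
}

#' Permuted-axis null dataset
#'
#' Returns the axis values (pseudotime or coordinates) under a uniform
#' random permutation of their assignment to cells; expression is left
#' untouched. Used to build null datasets for false-positive checks.
#'
#' @param axis Named pseudotime vector or coordinate matrix with rownames.
#' @param seed Integer seed.
#' @return The permuted axis with the original ids in the original order.
#' @export
make_null <- function(axis, seed) {
  set.seed(as.integer(seed))
  if (is.matrix(axis)) {
    out <- axis[sample.int(nrow(axis)), , drop = FALSE]
    rownames(out) <- rownames(axis)
  } else {
    out <- stats::setNames(axis[sample.int(length(axis))], names(axis))
  }
  out
}

#' Overlap proportion of two top-L gene lists
#'
#' `|top-L(a) intersect top-L(b)| / L`, the standard agreement measure for
#' ranked gene lists.
#'
#' @param rank_a,rank_b Character vectors of gene ids ordered best-first.
#' @param L Number of top genes to compare (`1 <= L <= min(lengths)`).
#' @return A number in `[0, 1]`.
#' @export
overlap_proportion <- function(rank_a, rank_b, L) {
  if (L <= 0) stop("'L' must be positive")
  if (L > min(length(rank_a), length(rank_b)))
    stop("'L' exceeds the length of a ranking")
  length(intersect(rank_a[seq_len(L)], rank_b[seq_len(L)])) / L
}

#' Area under the precision-recall curve of a gene ranking
#'
#' Trapezoidal area under the precision-recall curve evaluated at the
#' distinct score thresholds, so tied scores are handled as a single
#' operating point. Rank genes by `score` decreasing (pass `-pvalue` to
#' rank small p-values first).
#'
#' @param score Numeric vector; larger means more confidently positive.
#' @param label Logical (or 0/1) ground-truth labels.
#' @return The area, in `[0, 1]`.
#' @export
auprc <- function(score, label) {
  if (length(score) != length(label)) stop("length mismatch")
  label <- as.logical(label)
  P <- sum(label)
  if (P == 0 || P == length(label))
    stop("labels must contain both classes")
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  l <- label[o]
  # operating points at the end of each tied-score block
  last <- which(s != c(s[-1], NA))
  last <- c(last, length(s))
  last <- unique(last)
  tp <- cumsum(l)[last]
  pos <- last
  recall <- tp / P
  prec <- tp / pos
  sum(diff(c(0, recall)) * (prec + c(prec[1], prec[-length(prec)])) / 2)
}
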