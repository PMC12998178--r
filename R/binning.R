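# Optional pre-aggregation of cells into temporal or spatial bins before
# fitting. The bin becomes the observational unit: downstream fits and
# tests use the number of occupied bins in all df and BIC formulas, so
# p-values from binned and unbinned runs are not directly comparable.

#' Average expression within equal-width pseudotime bins
#'
#' Partitions the observed pseudotime range into `n_bins` equal-width
#' intervals (right-closed, except the first interval which includes its
#' left boundary) and averages each gene's expression within each occupied
#' bin. Empty bins are dropped.
#'
#' @param Y Genes x cells expression matrix.
#' @param t Per-cell pseudotime aligned to the columns of `Y`.
#' @param n_bins Number of intervals (default 100).
#'
#' @return A list with `Yb` (genes x occupied-bins means), `bin_centers`
#'   (interval midpoints), `bin_counts` (cells per occupied bin) and
#'   `mapping` (occupied-bin index per original cell).
#' @export
bin_temporal <- function(Y, t, n_bins = 100L) {
  if (n_bins < 2) stop("'n_bins' must be at least 2")
  Y <- as.matrix(Y)
  if (ncol(Y) != length(t)) stop("length of 't' must equal ncol(Y)")
  lo <- min(t)
  hi <- max(t)
  if (lo == hi) stop("degenerate axis: all pseudotime values identical")
  w <- (hi - lo) / n_bins
  idx <- as.integer(ceiling((t - lo) / w))
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- as.integer(n_bins)
  occ <- sort(unique(idx))
  if (length(occ) < 2)
    stop("degenerate binning: all cells fall in one bin")
  grp <- match(idx, occ)
  counts <- tabulate(grp, nbins = length(occ))
  Yb <- t(rowsum(t(Y), grp, reorder = TRUE)) /
    rep(counts, each = nrow(Y))
  colnames(Yb) <- paste0("bin", occ)
  list(Yb = Yb, bin_centers = lo + (occ - 0.5) * w,
       bin_counts = counts, mapping = grp)
}

#' Average expression within an evenly spaced spatial grid
#'
#' Overlays an evenly spaced `grid[1] x grid[2]` grid on the observed
#' coordinate ranges (per-axis equal-width edges; points exactly on an
#' interior edge go to the higher-index cell, the outer boundary belongs to
#' the outermost cell) and averages each gene's expression within each
#' occupied grid cell. Empty grid cells are dropped.
#'
#' @param Y Genes x spots expression matrix.
#' @param S `n x 2` coordinate matrix aligned to the columns of `Y`.
#' @param grid Integer pair of grid dimensions (default `c(100, 100)`).
#'
#' @return As [bin_temporal()], with `bin_centers` an occupied-bins x 2
#'   matrix of grid-cell centers.
#' @export
bin_spatial <- function(Y, S, grid = c(100L, 100L)) {
  grid <- as.integer(grid)
  if (length(grid) != 2 || any(grid < 2))
    stop("'grid' must be two integers >= 2")
  Y <- as.matrix(Y)
  S <- as.matrix(S)
  if (ncol(Y) != nrow(S)) stop("nrow(S) must equal ncol(Y)")
  axis_index <- function(s, g) {
    lo <- min(s)
    hi <- max(s)
    if (lo == hi) stop("degenerate axis: all coordinates identical")
    w <- (hi - lo) / g
    i <- as.integer(floor((s - lo) / w)) + 1L
    i[i < 1L] <- 1L
    i[i > g] <- g
    i
  }
  i1 <- axis_index(S[, 1], grid[1])
  i2 <- axis_index(S[, 2], grid[2])
  cell <- (i1 - 1L) * grid[2] + i2
  occ <- sort(unique(cell))
  if (length(occ) < 2)
    stop("degenerate binning: all spots fall in one grid cell")
  grp <- match(cell, occ)
  counts <- tabulate(grp, nbins = length(occ))
  Yb <- t(rowsum(t(Y), grp, reorder = TRUE)) /
    rep(counts, each = nrow(Y))
  colnames(Yb) <- paste0("bin", occ)
  o1 <- (occ - 1L) %/% grid[2] + 1L
  o2 <- (occ - 1L) %% grid[2] + 1L
  w1 <- (max(S[, 1]) - min(S[, 1])) / grid[1]
  w2 <- (max(S[, 2]) - min(S[, 2])) / grid[2]
  centers <- cbind(min(S[, 1]) + (o1 - 0.5) * w1,
                   min(S[, 2]) + (o2 - 0.5) * w2)
  rownames(centers) <- colnames(Yb)
  list(Yb = Yb, bin_centers = centers, bin_counts = counts, mapping = grp)
}
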