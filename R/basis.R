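# Clamped cubic B-spline bases with equidistant internal knots, and the
# 1-D / tensor-product design matrices shared by all genes.

#' Knot specification for a clamped cubic B-spline basis
#'
#' Places `K` equidistant internal knots strictly inside the observed range
#' of `values`. Boundary knots sit at the observed minimum and maximum with
#' multiplicity 4 (the clamped cubic convention), so the resulting basis
#' spans constants and linear functions on the interval.
#'
#' @param values Numeric vector of axis values (pseudotime or one spatial
#'   coordinate). Only the observed range is used.
#' @param K Single non-negative integer: the number of internal knots.
#'
#' @return An object of class `"knot_spec"`: a list with elements `K`,
#'   `boundary_lo`, `boundary_hi` and `internal_knots` (length `K`, sorted,
#'   strictly inside the boundary interval).
#'
#' @examples
#' make_knots(c(2, 10), K = 3)$internal_knots # 4 6 8
#' @export
make_knots <- function(values, K) {
  if (!is.numeric(values) || length(values) < 1)
    stop("'values' must be a non-empty numeric vector")
  if (!is.numeric(K) || length(K) != 1 || is.na(K) || K < 0 || K != floor(K))
    stop("'K' must be a single non-negative integer")
  lo <- min(values)
  hi <- max(values)
  if (!is.finite(lo) || !is.finite(hi))
    stop("axis values must be finite")
  if (lo == hi)
    stop("degenerate axis: all values identical")
  K <- as.integer(K)
  internal <- if (K >= 1) lo + seq_len(K) * (hi - lo) / (K + 1) else numeric(0)
  structure(
    list(K = K, boundary_lo = lo, boundary_hi = hi, internal_knots = internal),
    class = "knot_spec"
  )
}

#' Evaluate the identifiable cubic B-spline basis
#'
#' Evaluates the full clamped cubic B-spline basis (`K + 4` functions on `K`
#' internal knots) at `values` and drops the first function, so that
#' together with an explicit intercept the columns span the same space as
#' the full partition-of-unity basis while remaining identifiable. Values
#' outside the boundary interval (possible when a design is reused on new
#' points) are clamped to the nearest boundary.
#'
#' @param values Numeric vector of evaluation points.
#' @param knots A [make_knots()] specification.
#'
#' @return A `length(values) x (K + 3)` matrix; entries lie in `[0, 1]` and
#'   columns are ordered by knot position.
#' @export
bspline_basis <- function(values, knots) {
  if (!inherits(knots, "knot_spec"))
    stop("'knots' must be a knot_spec from make_knots()")
  if (length(values) == 0)
    stop("no evaluation points")
  x <- pmin(pmax(values, knots$boundary_lo), knots$boundary_hi)
  kn <- c(rep(knots$boundary_lo, 4), knots$internal_knots,
          rep(knots$boundary_hi, 4))
  B <- splines::splineDesign(kn, x, ord = 4)
  B[, -1, drop = FALSE]
}

#' Temporal (1-D) spline design matrix
#'
#' Builds the `n x (K + 4)` design matrix `[1 | b_1(t) ... b_{K+3}(t)]`
#' evaluated at the pseudotime values `t`, with knots placed from the
#' observed range of `t`. The design depends only on the axis values, so a
#' single hat matrix serves every gene measured on the same cells.
#'
#' @param t Numeric vector of per-cell pseudotime values.
#' @param K Number of equidistant internal knots.
#'
#' @return An object of class `"spline_design"`: a list with the design
#'   matrix `X`, column count `p = K + 4`, `axis_kind = "temporal"`, the
#'   `knots` (list of one knot_spec) and per-column `column_roles`.
#' @export
temporal_design <- function(t, K) {
  if (!is.numeric(t) || !all(is.finite(t)))
    stop("pseudotime values must be finite numerics")
  ks <- make_knots(t, K)
  B <- bspline_basis(t, ks)
  p <- ncol(B) + 1L
  if (length(t) <= p)
    warning("saturated or under-determined fit: n <= K + 4")
  X <- cbind(1, B)
  colnames(X) <- c("(Intercept)", paste0("b", seq_len(ncol(B))))
  structure(
    list(X = X, p = p, axis_kind = "temporal", knots = list(ks),
         column_roles = c("intercept", rep("marginal-axis1", ncol(B)))),
    class = "spline_design"
  )
}

#' Spatial (tensor-product) spline design matrix
#'
#' Builds the `n x (K + 4)^2` design matrix for a smooth surface over 2-D
#' coordinates: an intercept, `K + 3` marginal bases per axis, and all
#' `(K + 3)^2` pairwise products `b_{1,k1}(s1) * b_{2,k2}(s2)` in
#' row-major order (`k1` outer, `k2` inner). Each axis gets its own knots
#' from its own observed range, so fits are invariant to axis-wise
#' rescaling.
#'
#' @param S Numeric `n x 2` matrix of coordinates.
#' @param K Number of equidistant internal knots per axis.
#'
#' @return A `"spline_design"` with `p = (K + 4)^2`,
#'   `axis_kind = "spatial"` and two knot_specs in `knots`.
#' @export
spatial_design <- function(S, K) {
  S <- as.matrix(S)
  if (ncol(S) != 2)
    stop("'S' must have exactly two coordinate columns")
  if (!all(is.finite(S)))
    stop("spatial coordinates must be finite")
  ks1 <- make_knots(S[, 1], K)
  ks2 <- make_knots(S[, 2], K)
  B1 <- bspline_basis(S[, 1], ks1)
  B2 <- bspline_basis(S[, 2], ks2)
  q <- ncol(B1)
  # interactions in k1-outer / k2-inner order: column (k1-1)*q + k2
  inter <- B1[, rep(seq_len(q), each = q), drop = FALSE] *
    B2[, rep(seq_len(q), times = q), drop = FALSE]
  X <- cbind(1, B1, B2, inter)
  colnames(X) <- c(
    "(Intercept)", paste0("b1.", seq_len(q)), paste0("b2.", seq_len(q)),
    paste0("b1.", rep(seq_len(q), each = q), "xb2.",
           rep(seq_len(q), times = q))
  )
  structure(
    list(X = X, p = ncol(X), axis_kind = "spatial", knots = list(ks1, ks2),
         column_roles = c("intercept", rep("marginal-axis1", q),
                          rep("marginal-axis2", q),
                          rep("interaction", q * q))),
    class = "spline_design"
  )
}
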