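# Independent oracles used across the suite.

# Raw clamped cubic B-spline basis (all K+4 functions) by the textbook
# de Boor recursion, written without reference to the package's own basis
# code or to splines::splineDesign.
deboor_one <- function(x, i, k, kn, hi) {
  if (k == 1) {
    inside <- kn[i] <= x && x < kn[i + 1]
    at_end <- x == hi && kn[i + 1] == hi && kn[i] < kn[i + 1]
    return(as.numeric(inside || at_end))
  }
  a <- 0
  if (kn[i + k - 1] != kn[i])
    a <- (x - kn[i]) / (kn[i + k - 1] - kn[i]) *
      deboor_one(x, i, k - 1, kn, hi)
  b <- 0
  if (kn[i + k] != kn[i + 1])
    b <- (kn[i + k] - x) / (kn[i + k] - kn[i + 1]) *
      deboor_one(x, i + 1, k - 1, kn, hi)
  a + b
}

deboor_raw_basis <- function(x, lo, hi, internal) {
  kn <- c(rep(lo, 4), internal, rep(hi, 4))
  nb <- length(kn) - 4
  out <- matrix(0, length(x), nb)
  for (j in seq_along(x))
    for (i in seq_len(nb))
      out[j, i] <- deboor_one(x[j], i, 4, kn, hi)
  out
}

# Brute-force per-gene least squares through the normal equations.
oracle_fit_one <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  drop(X %*% beta)
}

oracle_fit_all <- function(X, Y) {
  t(apply(Y, 1, function(y) oracle_fit_one(X, y)))
}

# Small random expression fixture with ids.
random_expr <- function(m, n, seed, prefix = "c") {
  set.seed(seed)
  Y <- matrix(rnorm(m * n), m, n,
              dimnames = list(sprintf("g%03d", seq_len(m)),
                              paste0(prefix, seq_len(n))))
  Y
}
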