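test_that("equidistant internal knots are placed correctly", {
  expect_identical(make_knots(c(0, 1), 0)$internal_knots, numeric(0))
  expect_equal(make_knots(c(0, 1), 1)$internal_knots, 0.5)
  expect_equal(make_knots(c(2, 10), 3)$internal_knots, c(4, 6, 8))
  ks <- make_knots(runif(20, -3, 7), 4)
  expect_equal(diff(ks$internal_knots), rep(diff(ks$internal_knots)[1], 3))
  expect_error(make_knots(rep(2, 5), 1), "degenerate axis")
  expect_error(make_knots(c(0, 1), -1))
})

test_that("dropped-first basis matches the cubic Bernstein closed form", {
  ks <- make_knots(c(0, 1), 0)
  B <- bspline_basis(c(0, 0.5, 1), ks)
  expect_equal(B[1, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(B[2, ], c(0.375, 0.375, 0.125), ignore_attr = TRUE)
  expect_equal(B[3, ], c(0, 0, 1), ignore_attr = TRUE)
})

test_that("basis agrees with an independent de Boor recursion oracle", {
  set.seed(42)
  for (K in 0:10) {
    x <- runif(100, -1, 3)
    ks <- make_knots(x, K)
    raw <- deboor_raw_basis(x, ks$boundary_lo, ks$boundary_hi,
                            ks$internal_knots)
    # partition of unity of the raw K+4 basis
    expect_lt(max(abs(rowSums(raw) - 1)), 1e-12)
    B <- bspline_basis(x, ks)
    expect_lt(max(abs(B - raw[, -1])), 1e-10)
    expect_true(all(B >= 0 & B <= 1))
  }
})

test_that("evaluation points outside the boundary are clamped", {
  ks <- make_knots(c(0, 1), 2)
  expect_equal(bspline_basis(c(-5, 0), ks)[1, ], bspline_basis(0, ks)[1, ])
  expect_equal(bspline_basis(c(7, 1), ks)[1, ], bspline_basis(1, ks)[1, ])
  expect_error(bspline_basis(numeric(0), ks), "no evaluation points")
})

test_that("temporal design has p = K + 4 columns and a leading intercept", {
  t <- seq(0, 1, length.out = 40)
  for (K in c(0, 2, 5)) {
    d <- temporal_design(t, K)
    expect_equal(ncol(d$X), K + 4)
    expect_equal(d$p, K + 4)
    expect_true(all(d$X[, 1] == 1))
    expect_identical(d$column_roles[1], "intercept")
  }
  expect_warning(temporal_design(runif(4), 2), "under-determined")
  # tied pseudotime gives identical design rows (n = p here, hence the
  # saturation warning)
  d <- suppressWarnings(temporal_design(c(0, 0.3, 0.3, 1), 0))
  expect_identical(d$X[2, ], d$X[3, ])
})

test_that("spatial design has (K + 4)^2 columns in the documented order", {
  set.seed(7)
  S <- cbind(runif(60, 2, 9), runif(60, -1, 1))
  for (K in 0:1) {
    d <- spatial_design(S, K)
    expect_equal(d$p, (K + 4)^2)
    expect_equal(as.integer(table(d$column_roles)[c(
      "intercept", "marginal-axis1", "marginal-axis2", "interaction")]),
      c(1L, K + 3L, K + 3L, (K + 3L)^2))
  }
  # at (min1, min2) every dropped-first marginal basis vanishes
  S2 <- rbind(c(min(S[, 1]), min(S[, 2])), S)
  d <- spatial_design(S2, 0)
  expect_equal(d$X[1, ], c(1, rep(0, 15)), ignore_attr = TRUE)
  # interaction block is k1-outer / k2-inner
  q <- 3
  B1 <- bspline_basis(S2[, 1], d$knots[[1]])
  B2 <- bspline_basis(S2[, 2], d$knots[[2]])
  inter <- d$X[, (2 + 2 * q):ncol(d$X)]
  expect_equal(inter[, (2 - 1) * q + 3], B1[, 2] * B2[, 3],
               ignore_attr = TRUE)
  expect_error(spatial_design(cbind(rep(1, 10), runif(10)), 0),
               "degenerate axis")
})
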