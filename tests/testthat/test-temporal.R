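test_that("temporal BIC follows the closed form", {
  # residual mean square exactly 1 at n = 10
  y <- c(rep(1, 5), rep(-1, 5))
  expect_equal(bic_temporal(y, rep(0, 10), K = 0),
               5 * log(10) + 10 + 10 * log(2 * pi))
  # doubling the residual mean square adds n log 2
  expect_equal(bic_temporal(sqrt(2) * y, rep(0, 10), K = 0) -
                 bic_temporal(y, rep(0, 10), K = 0),
               10 * log(2))
  # a perfect fit prefers the smaller K through the penalty alone
  expect_lt(bic_temporal(y, y, K = 0), bic_temporal(y, y, K = 1))
})

test_that("BIC knot selection is parsimonious and matches brute force", {
  set.seed(31)
  n <- 500
  t <- runif(n)
  # pure-noise genes: the penalty dominates and K = 0 wins almost always
  Yn <- random_expr(100, n, seed = 32)
  sel <- select_K(Yn, t, candidates = 0:10)
  expect_gt(mean(sel$selected == 0), 0.8)
  # a three-hump oscillation with tiny noise needs internal knots
  y3 <- sin(2 * pi * 3 * t) + rnorm(n, sd = 0.05)
  Y3 <- rbind(osc = y3, const = rep(1, n), lin = 2 - t)
  colnames(Y3) <- paste0("c", seq_len(n))
  sel3 <- select_K(Y3, t, candidates = 0:10)
  expect_gt(sel3$selected[["osc"]], 0)
  expect_identical(sel3$selected[["const"]], 0L)
  expect_identical(sel3$selected[["lin"]], 0L)
  # brute-force verification: per-gene, per-K normal-equation fits
  for (g in rownames(Y3)) {
    bics <- vapply(0:10, function(K) {
      X <- temporal_design(t, K)$X
      bic_temporal(Y3[g, ], oracle_fit_one(X, Y3[g, ]), K, n)
    }, numeric(1))
    expect_identical(sel3$selected[[g]], (0:10)[which.min(bics)])
  }
  # candidates = {0} pins every gene at K = 0
  expect_true(all(select_K(Yn, t, candidates = 0)$selected == 0))
  # infeasible candidates are skipped with a warning
  expect_warning(select_K(Yn[, 1:8], t[1:8], candidates = c(0, 10)),
                 "skipping infeasible")
})

test_that("the F statistic handles constant, perfect and noisy genes", {
  set.seed(41)
  t <- runif(30)
  d <- temporal_design(t, 0)
  yc <- rep(2, 30)
  f <- fit_genes(rbind(yc), d)
  expect_equal(f_statistic(yc, f$Yhat[1, ], 0)$F, 0)
  yl <- 1 + 2 * t
  fl <- fit_genes(rbind(yl), d)
  sl <- f_statistic(yl, fl$Yhat[1, ], 0)
  expect_identical(sl$F, Inf)
  expect_equal(c(sl$df1, sl$df2), c(3, 26))
  expect_error(f_statistic(yl[1:4], yl[1:4], 0), "n > K \\+ 4")
})

test_that("null F statistics follow the exact F reference at small n", {
  set.seed(51)
  n <- 10
  t <- runif(n)
  Y <- matrix(rnorm(2000 * n), 2000)
  fit <- fit_temporal(Y, t, K = 0)
  res <- ftest_pvalues(fit, Y)
  ks <- suppressWarnings(stats::ks.test(res$F, stats::pf, 3, n - 4))
  expect_gt(ks$p.value, 0.01)
  # p-values of constants and perfect fits sit at the extremes
  Y2 <- rbind(const = rep(1, n), lin = t)
  r2 <- ftest_pvalues(fit_temporal(Y2, t, K = 0), Y2)
  expect_equal(r2$pvalue, c(1, 0))
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
})

test_that("Gamma calibration recovers the null shape and degrades safely", {
  set.seed(61)
  shapes <- replicate(1000, {
    splinegenes:::gamma_tail_pvalue(3, rgamma(100, shape = 2, rate = 1))$shape
  })
  expect_lt(abs(mean(shapes) - 2) / 2, 0.2)
  # an observed F far beyond all nulls lands deep in the Gamma tail
  g <- splinegenes:::gamma_tail_pvalue(50, rgamma(100, shape = 2, rate = 1))
  expect_lt(g$pvalue, 0.01)
  # degenerate nulls fall back to the empirical tail
  ge <- splinegenes:::gamma_tail_pvalue(1, rep(2, 100))
  expect_equal(ge$fallback, "empirical")
  expect_equal(ge$pvalue, (100 + 1) / (100 + 1))
})

test_that("the permutation test is reproducible and respects its contract", {
  set.seed(71)
  n <- 60
  t <- runif(n)
  Y <- rbind(sig = 3 * t + rnorm(n, sd = 0.3),
             random_expr(10, n, seed = 72))
  colnames(Y) <- paste0("c", seq_len(n))
  r1 <- suppressWarnings(permutation_test(Y, t, B = 30, seed = 9))
  r2 <- suppressWarnings(permutation_test(Y, t, B = 30, seed = 9))
  expect_identical(r1, r2)
  expect_lt(r1$pvalue[r1$gene_id == "sig"], 0.01)
  expect_equal(dim(attr(r1, "null_F")), c(11L, 30L))
  # the pseudotime-inference callback is honored
  called <- FALSE
  cb <- function(Ysub, tsub) { called <<- TRUE; tsub }
  suppressWarnings(permutation_test(Y, t, B = 2, seed = 9, infer = cb))
  expect_true(called)
  expect_error(permutation_test(Y, t, B = 1, seed = 1), "at least 2")
  expect_error(permutation_test(Y, t, B = 5, subsample_frac = 0, seed = 1))
})
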