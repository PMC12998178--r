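test_that("resampled scalability datasets follow the stated construction", {
  base <- random_expr(5, 20, seed = 101)
  r <- resample_scaling_temporal(base, 50, seed = 3)
  expect_equal(unname(r$t), as.numeric(1:50))
  expect_identical(r, resample_scaling_temporal(base, 50, seed = 3))
  expect_true(all(r$Y[1, ] %in% base[1, ])) # columns drawn from the base
  expect_error(resample_scaling_temporal(base, 1, seed = 1), "at least 2")

  rs <- resample_scaling_spatial(base, c(2, 3), seed = 4)
  expect_equal(unname(rs$S),
               cbind(c(1, 1, 1, 2, 2, 2), c(1, 2, 3, 1, 2, 3)))
  expect_equal(ncol(resample_scaling_spatial(base, c(5, 8), 1)$Y), 40)
})

test_that("ground-truth generators are pure functions of the seed", {
  a <- make_groundtruth(n_genes = 50, n = 40, seed = 7)
  b <- make_groundtruth(n_genes = 50, n = 40, seed = 7)
  expect_identical(a, b)
  d <- make_groundtruth(n_genes = 50, n = 40, seed = 8)
  expect_false(identical(a$Y, d$Y))
  s1 <- make_groundtruth(n_genes = 30, n = 40, mode = "spatial", seed = 7)
  expect_equal(dim(s1$axis), c(40L, 2L))
})

test_that("the variable-gene fraction is honored exactly", {
  g <- make_groundtruth(n_genes = 123, n = 30, fraction_variable = 0.1,
                        seed = 5)
  expect_equal(sum(g$truth), round(0.1 * 123))
  g0 <- make_groundtruth(n_genes = 50, n = 30, fraction_variable = 0,
                         seed = 5)
  expect_equal(sum(g0$truth), 0)
  # zero effect size leaves labeled genes signal-free
  ge <- make_groundtruth(n_genes = 40, n = 200, effect_size = 0, seed = 6)
  sig <- ge$Y[ge$truth, , drop = FALSE]
  expect_lt(max(abs(apply(sig, 1, function(y)
    cor(y, ge$axis)))), 0.25)
})

test_that("axis permutation conserves values and is reproducible", {
  t <- stats::setNames(runif(20), paste0("c", 1:20))
  p1 <- make_null(t, seed = 2)
  expect_identical(p1, make_null(t, seed = 2))
  expect_equal(sort(unname(p1)), sort(unname(t)))
  expect_identical(names(p1), names(t))
  S <- cbind(runif(10), runif(10))
  rownames(S) <- paste0("s", 1:10)
  pS <- make_null(S, seed = 3)
  expect_identical(rownames(pS), rownames(S))
  expect_equal(sort(unname(pS[, 1])), sort(unname(S[, 1])))
})

test_that("overlap proportion matches set arithmetic", {
  a <- c("g1", "g2", "g3", "g4")
  b <- c("g2", "g1", "g5", "g6")
  expect_equal(overlap_proportion(a, b, 2), 1)
  expect_equal(overlap_proportion(a, b, 4), 0.5)
  expect_equal(overlap_proportion(a, a, 3), 1)
  expect_equal(overlap_proportion(a, c("g7", "g8", "g9", "g0"), 4), 0)
  expect_error(overlap_proportion(a, b, 0), "positive")
  expect_error(overlap_proportion(a, b, 9), "exceeds")
})

test_that("precision-recall area behaves at the extremes and on ties", {
  expect_equal(auprc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # hand-computed trapezoid for an interleaved ranking
  expect_equal(auprc(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE)), 19 / 24)
  # all scores tied: a single operating point at the prevalence
  expect_equal(auprc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auprc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})
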