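test_that("identical independent groups yield a null omnibus and no post-hocs", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res <- compareIndependentGroups(g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_null(res$posthoc)
})

test_that("well-separated groups trigger the full two-stage post-hoc chain", {
  g <- list(lo = 1:8, mid = 11:18, hi = 21:28)
  res <- compareIndependentGroups(g)
  expect_lt(res$p, 0.05)
  expect_true(all(res$posthoc$dunn$significant))
  expect_equal(nrow(res$posthoc$ranksum), 3L)
  ## one-sided directions follow the medians
  expect_true(all(grepl(">", res$posthoc$ranksum$direction)))
  expect_true(all(res$posthoc$ranksum$p < 0.05))
})

test_that("two groups reduce to the rank-sum path", {
  res <- compareIndependentGroups(list(a = 1:5, b = 6:10))
  expect_equal(res$test, "wilcoxon_rank_sum")
  expect_error(compareIndependentGroups(list(a = 1, b = 1:3)), "at least 2")
})

test_that("omnibus type-I error is calibrated under the global null", {
  set.seed(17)
  rej <- mean(replicate(500, {
    g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
    stats::kruskal.test(g)$p.value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("paired comparisons run Friedman then corrected signed-rank tests", {
  m <- cbind(a = c(5, 6, 7, 8, 9, 10, 11, 12),
             b = c(5, 6, 7, 8, 9, 10, 11, 12))
  ident <- comparePairedConditions(cbind(m, c = m[, 1]))
  expect_equal(ident$statistic, 0, tolerance = 1e-12)
  expect_null(ident$posthoc)

  set.seed(18)
  a <- rnorm(12)
  shifted <- cbind(a = a, b = a + 2, c = a + 2.1)
  res <- comparePairedConditions(shifted)
  expect_lt(res$p, 0.05)
  expect_equal(nrow(res$posthoc), 3L)
  expect_true(all(res$posthoc$pCorrected >= res$posthoc$p - 1e-12))
  ab <- res$posthoc[res$posthoc$pair == "a vs b", ]
  expect_lt(ab$pCorrected, 0.05)
  ## Bonferroni correction is the simple multiple
  resB <- comparePairedConditions(shifted, correction = "bonferroni")
  expect_equal(resB$posthoc$pCorrected,
               pmin(1, resB$posthoc$p * 3), tolerance = 1e-12)
  ## small n uses the exact signed-rank distribution without error
  small <- comparePairedConditions(cbind(a = c(1, 2, 3), b = c(4, 5, 6),
                                         c = c(1.1, 2.1, 3.1)))
  expect_true(all(small$posthoc$p >= 0 & small$posthoc$p <= 1))
})

test_that("poolability is a two-sided rank-sum gate at p > 0.05", {
  set.seed(19)
  x <- rnorm(20); y <- rnorm(20)
  expect_true(checkPoolability(x, y)$poolable)
  expect_false(checkPoolability(1:8, 101:108)$poolable)
  expect_true(checkPoolability(c(1, 1, 1), c(1, 1, 1))$poolable)
  expect_error(checkPoolability(numeric(0), 1:3), "empty")
})

test_that("session-value correlations report Bonferroni-corrected p-values", {
  x <- c(1, 2, 3, 4, 5)
  res <- correlateSessionValues(x, x)
  expect_equal(res$r, 1)
  expect_equal(res$pCorrected, min(1, res$p * 3))
  expect_error(correlateSessionValues(x, rep(2, 5)), "zero variance")
  expect_error(correlateSessionValues(1:2, 1:2), "at least 3")
  ## null calibration: |r| exceeds the two-sided critical value ~5% of the time
  set.seed(20)
  n <- 72
  crit <- qt(0.975, n - 2) / sqrt(n - 2 + qt(0.975, n - 2)^2)
  rate <- mean(replicate(800, abs(cor(rnorm(n), rnorm(n))) > crit))
  expect_gt(rate, 0.03); expect_lt(rate, 0.08)
})
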