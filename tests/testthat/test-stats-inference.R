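test_that("identical normal samples take the t branch with one-tailed p = 0.5", {
  set.seed(1)
  x <- rnorm(20)
  res <- adaptiveTwoSampleTest(x, x, tail = "greater")
  expect_match(res$test, "^t ")
  expect_equal(res$p, 0.5)
})

test_that("separated normal samples give a strongly significant t test", {
  set.seed(2)
  x <- rnorm(20, 2, 1); y <- rnorm(20, 0, 1)
  res <- adaptiveTwoSampleTest(x, y, tail = "greater")
  expect_match(res$test, "^t ")
  expect_lt(res$p, 0.001)
  # the opposite tail is correspondingly non-significant
  expect_gt(adaptiveTwoSampleTest(x, y, tail = "less")$p, 0.999)
})

test_that("skewed samples fail the normality gate and take Mann-Whitney", {
  set.seed(3)
  x <- rexp(30); y <- rexp(30) + 1
  res <- adaptiveTwoSampleTest(y, x, tail = "greater")
  expect_equal(res$test, "mann-whitney")
  expect_lt(res$adPX, 0.05)   # decision trail records the gate
  expect_lt(res$p, 0.05)
})

test_that("small and degenerate samples are routed safely", {
  expect_error(adaptiveTwoSampleTest(1:2, 1:5), "at least 3")
  res <- adaptiveTwoSampleTest(rep(1, 5), rep(2, 5))
  expect_equal(res$test, "degenerate")
  expect_true(is.na(res$p))
  # n < 8: Anderson-Darling unavailable, Mann-Whitney branch
  set.seed(4)
  res2 <- adaptiveTwoSampleTest(rnorm(5), rnorm(5), tail = "greater")
  expect_equal(res2$test, "mann-whitney")
})

test_that("BH adjustment reproduces the hand-worked step-up example", {
  adj <- bhFdrAdjust(c(0.01, 0.02, 0.2, 0.9))
  expect_equal(adj$pAdj, c(0.04, 0.04, 0.2 * 4 / 3, 0.9))
  expect_equal(adj$rejected, c(TRUE, TRUE, FALSE, FALSE))
  # all-ones: nothing rejected
  expect_false(any(bhFdrAdjust(rep(1, 6))$rejected))
  # single p: identity, rejected at 0.05 <= 0.1
  one <- bhFdrAdjust(0.05)
  expect_equal(one$pAdj, 0.05)
  expect_true(one$rejected)
  # empty input
  expect_equal(nrow(bhFdrAdjust(numeric())), 0)
})

test_that("BH agrees with the brute-force oracle on 1,000 random vectors", {
  set.seed(5)
  for (i in 1:1000) {
    m <- sample(1:50, 1)
    p <- runif(m)
    expect_equal(bhFdrAdjust(p)$pAdj, bhOracle(p))
  }
})

test_that("adjusted p-values are monotone and never below raw", {
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- bhFdrAdjust(p)
    expect_true(all(adj$pAdj >= adj$p))
    o <- order(p)
    expect_true(all(diff(adj$pAdj[o]) >= -1e-12))
  }
})

test_that("significance tiers use exclusive figure-legend thresholds", {
  expect_equal(significanceTier(c(0.09, 0.03, 0.005, 0.1, 0.5, 0.05, 0.01)),
               c("*", "**", "***", "ns", "ns", "*", "**"))
  expect_true(is.na(significanceTier(NA_real_)))
})

test_that("family adjustment appends consistent columns", {
  set.seed(7)
  fam <- do.call(rbind, lapply(1:4, function(i)
    adaptiveTwoSampleTest(rnorm(10, i / 2), rnorm(10), tail = "greater",
                          label = paste("cmp", i))))
  fam <- adjustComparisonFamily(fam, q = 0.1)
  expect_equal(fam$pAdj, bhOracle(fam$p))
  expect_equal(fam$rejected, fam$pAdj <= 0.1)
  expect_equal(fam$tier, significanceTier(fam$pAdj))
})
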