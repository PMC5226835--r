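# Distribution summaries and rank-sum comparisons.

test_that("summaries use the documented type-7 quantile estimator", {
  s <- summarizeDistribution(c(1, 2, 3, 4, 5))
  expect_equal(s@median, 3)
  expect_equal(s@q1, 2)
  expect_equal(s@q3, 4)
  expect_equal(s@p5, 1.2)
  expect_equal(s@p95, 4.8)
  expect_equal(s@range90, 3.6)
  expect_equal(s@iqr, 2)
  expect_equal(s@medianCI, 3 + c(-1, 1) * 1.57 * 2 / sqrt(5))
  expect_error(summarizeDistribution(1), "two values")
})

test_that("constant samples collapse all quantiles", {
  s <- summarizeDistribution(rep(2.5, 40))
  expect_equal(s@range90, 0)
  expect_equal(s@iqr, 0)
  expect_equal(s@median, 2.5)
})

test_that("summaries are permutation-invariant and scale equivariant", {
  set.seed(51)
  x <- rlnorm(200)
  a <- summarizeDistribution(x)
  b <- summarizeDistribution(sample(x))
  expect_equal(a@median, b@median)
  expect_equal(a@range90, b@range90)
  sc <- summarizeDistribution(3 * x)
  expect_equal(sc@median, 3 * a@median)
  expect_equal(sc@iqr, 3 * a@iqr)
  expect_equal(sc@range90, 3 * a@range90)
})

test_that("rank-sum comparison behaves like the exact Mann-Whitney test", {
  # identical samples: p at the null center
  x <- c(1, 2, 3, 4, 5)
  expect_gt(compareDistributions(x, x), 0.9)
  # completely separated tiny samples: smallest attainable two-sided p
  expect_equal(compareDistributions(c(1, 2, 3), c(100, 101, 102)), 0.1)
  # symmetry
  set.seed(52)
  a <- rnorm(30)
  b <- rnorm(30, 1)
  expect_equal(compareDistributions(a, b), compareDistributions(b, a))
  expect_error(compareDistributions(numeric(0), 1), "nonempty")
})

test_that("fold changes divide the chosen statistic", {
  a <- summarizeDistribution(c(0.7, 0.8, 0.9))
  b <- summarizeDistribution(c(0.05, 0.1, 0.15))
  expect_equal(foldChange(a, b, "median"), 8)
  expect_equal(foldChange(a, a, "median"), 1)
  expect_equal(foldChange(a, a, "range90"), 1)
  z <- summarizeDistribution(rep(1, 10))
  expect_error(foldChange(a, z, "iqr"), "zero")
})
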