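test_that("paired t matches the textbook formula on a hand-checkable case", {
  # differences 1, 2, 3: mean 2, sd 1, t = 2 * sqrt(3), df = 2
  res <- paired_comparison(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$statistic, 2 * sqrt(3))
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-2 * sqrt(3), 2))
  expect_equal(res$estimate, 2)
})

test_that("paired t degenerate cases are flagged, identical series give p = 1", {
  res <- paired_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- paired_comparison(c(2, 3, 4), c(1, 2, 3))
  expect_true(is.infinite(res2$statistic))
  expect_true(res2$degenerate)
  expect_equal(res2$p_value, 0)
})

test_that("paired t is invariant to a common additive shift", {
  set.seed(12)
  x <- rnorm(10)
  y <- rnorm(10)
  r1 <- paired_comparison(x, y)
  r2 <- paired_comparison(x + 17, y + 17)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("Welch t has Satterthwaite df and sign symmetry", {
  set.seed(13)
  a <- rnorm(20, 0, 1)
  b <- rnorm(10, 0, 2)
  res <- welch_comparison(a, b)
  # hand-computed Welch-Satterthwaite df
  va <- var(a) / 20
  vb <- var(b) / 10
  df_hand <- (va + vb)^2 / (va^2 / 19 + vb^2 / 9)
  expect_equal(res$df, df_hand)
  expect_lt(res$df, 28)
  swapped <- welch_comparison(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)
  # identical groups: t = 0
  expect_equal(welch_comparison(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  # clear separation with tiny jitter
  sep <- welch_comparison(c(0, 0, 0, 0) + rnorm(4, 0, 1e-6),
                          c(1, 1, 1, 1) + rnorm(4, 0, 1e-6))
  expect_lt(sep$p_value, 0.01)
})

test_that("log10(x + 1) handles zeros and rejects negatives", {
  expect_equal(log10_plus_one(c(0, 9, 99)), c(0, 1, 2))
  expect_error(log10_plus_one(c(1, -2)), "non-negative")
})

test_that("land-use model: flat data gives F = 0 with all Tukey p = 1", {
  d <- data.frame(value = rep(0.25, 16),
                  class = rep(c("field", "hedge", "building", "road"), 4))
  res <- landuse_model(d)
  expect_equal(res$F_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_true(all(res$pairwise$p_tukey == 1))
})

test_that("a 10-SD shifted class lights up exactly its three comparisons", {
  set.seed(14)
  base <- rnorm(30, 0, 1)
  d <- data.frame(
    value = c(rnorm(10, 0, 1), rnorm(10, 0, 1), rnorm(10, 10, 1),
              rnorm(10, 0, 1)),
    class = rep(c("building", "field", "hedge", "road"), each = 10)
  )
  res <- landuse_model(d)
  expect_lt(res$p_value, 0.001)
  hedge_pairs <- grepl("hedge", res$pairwise$pair)
  expect_true(all(res$pairwise$p_tukey[hedge_pairs] < 0.001))
  expect_true(all(res$pairwise$p_tukey[!hedge_pairs] > 0.05))
})

test_that("balanced two-class F equals the squared pooled t", {
  set.seed(15)
  a <- rnorm(12, 0, 1)
  b <- rnorm(12, 0.8, 1)
  res <- landuse_model(data.frame(value = c(a, b),
                                  class = rep(c("field", "hedge"), each = 12)))
  t_pooled <- t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(res$F_statistic, unname(t_pooled^2))
})

test_that("Tukey-adjusted p is never below the raw pairwise p", {
  set.seed(16)
  for (r in 1:5) {
    d <- data.frame(
      value = rnorm(40, rep(c(0, 0.5, 1, 0.2), each = 10), 1),
      class = rep(c("building", "field", "hedge", "road"), each = 10)
    )
    res <- landuse_model(d)
    expect_true(all(res$pairwise$p_tukey >= res$pairwise$p_raw - 1e-12))
  }
})
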