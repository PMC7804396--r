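test_that("signed-rank test handles degenerate and extreme cases analytically", {
  x <- c(3, 5, 1, 2)
  res <- wilcoxon_signed_rank(x, x)
  expect_identical(res$p_value, 1)
  expect_identical(res$statistic, 4 * 5 / 4)
  expect_identical(res$flags, "degenerate")

  # n = 6 all-positive differences: one-tailed 1/64, two-sided 2/64
  a <- c(10, 11, 12, 13, 14, 15)
  b <- a - c(1, 2, 3, 4, 5, 6)
  res2 <- wilcoxon_signed_rank(a, b)
  expect_identical(res2$mode, "exact")
  expect_identical(res2$statistic, 21)
  expect_equal(res2$p_value, 2 / 64, tolerance = 1e-12)
})

test_that("exact signed-rank p equals full sign enumeration for n <= 10", {
  set.seed(5)
  for (i in 1:8) {
    n <- sample(5:10, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    res <- wilcoxon_signed_rank(a, b, mode = "exact")
    expect_equal(res$p_value, enumerate_signed_rank_p(a - b),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank test is antisymmetric in its arguments", {
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(12)
    b <- rnorm(12)
    r1 <- wilcoxon_signed_rank(a, b)
    r2 <- wilcoxon_signed_rank(b, a)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    n <- r1$n
    expect_equal(r1$statistic + r2$statistic, n * (n + 1) / 2)
    expect_equal(r1$z, -r2$z, tolerance = 1e-12)
  }
})

test_that("tied differences fall back to the corrected normal approximation", {
  a <- c(5, 6, 7, 8, 9, 10)
  b <- c(4, 5, 6, 7, 8, 9)  # all |d| = 1: fully tied
  expect_warning(res <- wilcoxon_signed_rank(a, b, mode = "exact"), "tied")
  expect_identical(res$mode, "approx")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("Friedman statistic matches the rank formula, including the 3x3 worked case", {
  ordered3 <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), nrow = 3, byrow = TRUE)
  res <- friedman_rank_test(ordered3)
  expect_equal(res$statistic, 6, tolerance = 1e-12)
  expect_identical(res$df, 2)

  same <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  res0 <- friedman_rank_test(matrix(5, 4, 3))
  expect_identical(res0$statistic, 0)
  expect_identical(res0$p_value, 1)

  set.seed(13)
  for (i in 1:6) {
    m <- matrix(rnorm(40), nrow = 10, ncol = 4)
    if (i > 3) m <- round(m)  # induce ties
    res <- friedman_rank_test(m)
    expect_equal(res$statistic, friedman_formula(m), tolerance = 1e-10)
    expect_identical(res$df, 3)
    expect_equal(res$p_value, pchisq(res$statistic, 3, lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  incomplete <- matrix(c(1, 2, NA, 4, 5, 6), nrow = 2)
  expect_error(friedman_rank_test(incomplete), "incomplete")
  expect_error(friedman_rank_test(matrix(1:3, ncol = 1)), "2 subjects")
})

test_that("Dunn-Bonferroni pairwise comparisons match the closed-form oracle", {
  # identical columns: every pair is null
  res_id <- dunn_posthoc(matrix(2, 6, 3))
  expect_true(all(res_id$adjusted_p == 1))
  expect_true(all(res_id$statistic == 0))

  # two conditions: a single pair, so adjustment changes nothing
  set.seed(3)
  m2 <- matrix(rnorm(20), 10, 2)
  res2 <- dunn_posthoc(m2)
  expect_identical(nrow(res2), 1L)
  expect_equal(res2$adjusted_p, res2$p_value, tolerance = 1e-12)

  # seeded 8x4 matrix against the z / adjusted-p formula
  set.seed(8)
  m <- matrix(rnorm(32), 8, 4)
  colnames(m) <- c("control", "c1", "c2", "c3")
  res <- dunn_posthoc(m)
  expect_identical(nrow(res), 6L)
  ranks <- t(apply(m, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(4 * 5 / (6 * 8))
  pairs <- combn(4, 2)
  for (q in 1:6) {
    i <- pairs[1, q]; j <- pairs[2, q]
    z <- (rbar[i] - rbar[j]) / se
    p <- 2 * pnorm(-abs(z))
    row <- res[res$comparison == paste(colnames(m)[i], "Vs", colnames(m)[j]), ]
    expect_equal(row$statistic, unname(z), tolerance = 1e-12)
    expect_equal(row$adjusted_p, min(1, p * 6), tolerance = 1e-12)
  }
  # Bonferroni adjustment is monotone and capped at 1
  expect_true(all(res$adjusted_p >= res$p_value))
  expect_true(all(res$adjusted_p <= 1))
})

test_that("Spearman correlation equals rank-then-Pearson and honours exactness rules", {
  expect_equal(spearman_rank(1:10, (1:10)^3)$statistic, 1, tolerance = 1e-12)
  expect_equal(spearman_rank(1:10, -(1:10))$statistic, -1, tolerance = 1e-12)

  set.seed(4)
  x <- rnorm(20)
  y <- rnorm(20)
  res <- spearman_rank(x, y)
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  expect_identical(res$mode, "approx")

  # exact route (n <= 8, tie-free) agrees with the reference distribution
  x8 <- rnorm(8); y8 <- rnorm(8)
  mine <- spearman_rank(x8, y8)
  ref <- suppressWarnings(cor.test(x8, y8, method = "spearman", exact = TRUE))
  expect_identical(mine$mode, "exact")
  expect_equal(mine$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)

  degen <- spearman_rank(rep(1, 5), rnorm(5))
  expect_true(is.na(degen$statistic))
  expect_identical(degen$flags, "degenerate")
})
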