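test_that("ICC(2,1) distinguishes agreement from consistency", {
  set.seed(15)
  base <- rnorm(10, 10, 2)
  # two identical raters: perfect agreement
  expect_equal(icc(cbind(base, base))$icc, 1, tolerance = 1e-12)

  # rater 2 offset by a constant large against the case variance:
  # agreement drops well below 1 even though consistency would be perfect
  r <- icc(cbind(base, base + 6))
  expect_lt(r$icc, 0.6)
  expect_equal(r$icc, brute_icc21(cbind(base, base + 6)), tolerance = 1e-12)

  expect_error(icc(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc(matrix(rnorm(4), 4, 1)), "2 cases and 2 raters")
})

test_that("ICC point estimate and CI match an independent implementation", {
  # 8 x 3 table; reference ICC(A,1) = 0.927676 with 95% CI [0.78, 0.98]
  # computed independently with a two-way mixed-model ICC routine
  x <- matrix(c(9.7564, 9.6922, 10.2474,
                10.7759, 10.6502, 10.1323,
                9.4371, 9.7994, 8.7796,
                7.99, 7.2682, 7.574,
                8.1698, 8.9731, 8.4569,
                8.1523, 8.0951, 7.9232,
                8.8619, 9.8509, 10.096,
                12.7371, 11.9154, 12.4416), 8, 3, byrow = TRUE)
  r <- icc(x)
  expect_equal(r$icc, 0.927676, tolerance = 1e-6)
  expect_equal(round(r$ci_lo, 2), 0.78)
  expect_equal(round(r$ci_hi, 2), 0.98)
})

test_that("ICC equals the brute-force mean-squares computation to 1e-10", {
  set.seed(16)
  for (i in 1:20) {
    n <- sample(4:20, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n, 5, 2), n, k) + matrix(rnorm(n * k, 0, 0.7), n, k) +
      rep(rnorm(k, 0, 0.3), each = n)
    expect_equal(icc(x)$icc, brute_icc21(x), tolerance = 1e-10)
  }
})

test_that("simulated rater pairs land in the variance-ratio prediction", {
  # case SD 1, error SD 0.1: population ICC = 1 / (1 + 0.01)
  set.seed(17)
  vals <- replicate(200, {
    cases <- rnorm(10, 0, 1)
    icc(cbind(cases + rnorm(10, 0, 0.1), cases + rnorm(10, 0, 0.1)))$icc
  })
  q <- quantile(vals, c(0.025, 0.975))
  expect_gt(q[1], 0.95)
  expect_lte(q[2], 1)
})

test_that("exact Wilcoxon signed rank matches enumeration, including ties", {
  w <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))
  expect_equal(w$statistic, 6)
  expect_equal(w$p_value, 0.25)

  # antisymmetric differences: p = 1
  w2 <- wilcoxon_signed_rank(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(w2$p_value, 1)

  set.seed(18)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    d <- round(rnorm(n, 0.3, 1) * 2) / 2  # plenty of ties
    while (sum(d != 0) < 3) d <- round(rnorm(n, 0.3, 1) * 2) / 2
    w <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_equal(w$p_value, brute_wilcoxon_p(d), tolerance = 1e-12)
  }

  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_error(wilcoxon_signed_rank(1:3, 1:2), "equal length")
  # zero differences are dropped and counted
  w3 <- wilcoxon_signed_rank(c(1, 2, 3, 5), c(1, 1, 1, 1))
  expect_equal(w3$n_zero, 1)
  expect_equal(w3$n_used, 3)
})

test_that("large-sample Wilcoxon uses the tie-corrected normal approximation", {
  set.seed(19)
  x <- round(rnorm(40, 0.4, 1), 1)
  y <- rep(0, 40)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("summaries report mean, absolute mean, and flag single values", {
  s <- summarize_values(c(-1, 1))
  expect_equal(s$mean, 0)
  expect_equal(s$abs_mean, 1)
  s2 <- summarize_values(c(1, 3))
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, sqrt(2))
  s3 <- summarize_values(5)
  expect_true(s3$sd_undefined)
  expect_true(is.na(s3$sd))
})
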