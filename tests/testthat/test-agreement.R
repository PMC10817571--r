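test_that("Spearman handles monotone data, the hand-worked triple and ties", {
  x <- 1:10
  expect_equal(spearman_corr(x, exp(x))$rs, 1)
  expect_equal(spearman_corr(x, -x^3)$rs, -1)
  expect_equal(spearman_corr(c(1, 2, 3), c(3, 1, 2))$rs, -0.5, tolerance = 1e-12)

  set.seed(26)
  for (i in 1:20) {
    a <- sample(1:5, 12, replace = TRUE)  # heavy ties
    b <- sample(1:5, 12, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    ours <- spearman_corr(a, b)$rs
    ref <- suppressWarnings(
      stats::cor.test(a, b, method = "spearman", exact = FALSE)$estimate)
    expect_equal(ours, unname(ref), tolerance = 1e-12)
  }
  expect_error(spearman_corr(rep(1, 5), 1:5),
               class = "nervetrace_undefined_correlation")
  expect_error(spearman_corr(1:2, 1:2), class = "nervetrace_size_error")
})

test_that("t-approximation p-values track the exact permutation law at tiny n", {
  set.seed(27)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6) + 0.5 * x
    res <- spearman_corr(x, y)
    p_exact <- oracle_perm_spearman_p(x, y)
    expect_lt(abs(res$p - p_exact), 0.06)
  }
  # strong monotone association: both routes call it significant
  res <- spearman_corr(1:7, c(1, 2, 3, 4, 5, 7, 6))
  expect_lt(res$p, 0.05)
  expect_lt(oracle_perm_spearman_p(1:7, c(1, 2, 3, 4, 5, 7, 6)), 0.05)
})

test_that("interpretation bands follow the published cut-points exactly", {
  band <- nervetrace:::correlation_band
  expect_identical(band(0.2), "weak")
  expect_identical(band(0.39), "weak")
  expect_identical(band(0.4), "moderate")
  expect_identical(band(0.517), "moderate")  # not strong
  expect_identical(band(0.59), "moderate")
  expect_identical(band(0.6), "strong")
  expect_identical(band(0.79), "strong")
  expect_identical(band(0.395), "other")
  expect_identical(band(0.85), "other")
  expect_identical(band(0.1), "other")
  expect_identical(band(-0.45), "moderate")  # bands act on |rs|
})

test_that("pooled Student's t matches the textbook formula and conventions", {
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  # oracle: explicit pooled-variance formula
  a <- c(2.3, 3.1, 2.8, 3.5); b <- c(1.9, 2.2, 2.6)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(two_sample_t(a, b)$t, t_oracle, tolerance = 1e-12)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  shifted <- two_sample_t(a + 100, b + 100)
  expect_equal(shifted$t, t_oracle, tolerance = 1e-9)

  expect_equal(two_sample_t(c(1, 1), c(1, 1))$p, 1)
  expect_equal(two_sample_t(c(1, 1), c(2, 2))$p, 0)
  pt_ <- two_sample_t(c(1, 2, 4), c(0, 1, 2), paired = TRUE)
  expect_equal(pt_$df, 2)
})

test_that("Bland-Altman sign convention, limits and coverage behave as defined", {
  ref <- c(10, 12, 14, 16, 18)
  ba0 <- bland_altman(ref, ref)
  expect_equal(ba0$mean_diff, 0); expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$coverage, 1)

  ba2 <- bland_altman(ref, ref - 2)  # test underestimates by 2
  expect_equal(ba2$mean_diff, 2); expect_equal(ba2$sd_diff, 0)
  expect_equal(ba2$loa_low, 2); expect_equal(ba2$loa_high, 2)

  set.seed(28)
  d <- rnorm(1000, 0.5, 1)
  ba <- bland_altman(100 + d, rep(100, 1000))
  expect_lt(abs(ba$mean_diff - 0.5), 0.1)
  expect_lt(abs(ba$coverage - 0.95), 0.02)
  expect_lte(ba$loa_low, ba$mean_diff)
  expect_lte(ba$mean_diff, ba$loa_high)
  expect_error(bland_altman(1:4, 1:5), class = "nervetrace_size_error")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(29)
  for (i in 1:15) {
    x <- rnorm(30); y <- rnorm(30) + 0.8 * x
    r0 <- spearman_corr(x, y)$rs
    expect_equal(spearman_corr(exp(x), y)$rs, r0, tolerance = 1e-12)
    expect_equal(spearman_corr(x, 3 * y - 7)$rs, r0, tolerance = 1e-12)
    expect_equal(spearman_corr(x, atan(y))$rs, r0, tolerance = 1e-12)
  }
})
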