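test_that("pooled t-test handles identity, shift and degenerate cases", {
  a <- c(1, 2, 3)
  out <- ttest_pooled(a, a)
  expect_equal(out$t_stat, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$df, 4)

  out <- ttest_pooled(a, a + 10)
  expect_lt(out$p_value, 0.01)

  # zero pooled variance: equal means -> p = 1; unequal -> degenerate
  out <- ttest_pooled(c(2, 2), c(2, 2))
  expect_equal(out$p_value, 1)
  out <- ttest_pooled(c(2, 2), c(5, 5))
  expect_true(out$degenerate)
  expect_equal(out$p_value, 0)

  expect_error(ttest_pooled(1, c(1, 2)), "n >= 2")
})

test_that("raw-sample and summary-statistic tests agree to 1e-12", {
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    raw <- ttest_pooled(a, b)
    summ <- ttest_from_summary(mean(a), sd(a), length(a),
                               mean(b), sd(b), length(b))
    expect_equal(raw$t_stat, summ$t_stat, tolerance = 1e-12)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
    expect_equal(raw$df, summ$df)
  }
})

test_that("printed per-class summaries reproduce the reported p-values", {
  # the four discriminating features, from their published group summaries
  expect_equal(round(ttest_from_summary(101.5, 25.4, 43, 124.5, 39.8, 73)$p_value, 3), 0.001)
  expect_equal(round(ttest_from_summary(27.5, 6.9, 43, 33.4, 10.8, 73)$p_value, 3), 0.002)
  expect_equal(round(ttest_from_summary(10.4, 1.3, 43, 11.4, 1.9, 73)$p_value, 3), 0.003)
  expect_equal(round(ttest_from_summary(27.9, 7.3, 43, 33.4, 10.8, 73)$p_value, 3), 0.004)
  expect_equal(ttest_from_summary(5, 1, 10, 5, 2, 10)$p_value, 1)
})

test_that("t-test p-values agree with a permutation oracle on small samples", {
  set.seed(12)
  for (i in 1:4) {
    a <- rnorm(6); b <- rnorm(7, mean = 1)
    p_t <- ttest_pooled(a, b)$p_value
    pool <- c(a, b)
    obs <- abs(mean(a) - mean(b))
    perm <- replicate(4000, {
      idx <- sample(length(pool), length(a))
      abs(mean(pool[idx]) - mean(pool[-idx]))
    })
    p_perm <- mean(perm >= obs - 1e-12)
    expect_lt(abs(p_t - p_perm), 0.05)  # Monte-Carlo + normality slack
  }
})

test_that("feature correlations: diagonal, affine invariance, block recovery", {
  set.seed(13)
  tab <- planted_table(30, 30, shift = 0)
  tab$contrast <- 2 * tab$autocorrelation + 1
  R <- feature_correlations(tab, c("autocorrelation", "contrast", "energy"))
  expect_equal(diag(R), c(autocorrelation = 1, contrast = 1, energy = 1))
  expect_equal(R["autocorrelation", "contrast"], 1)
  expect_equal(R, t(R))

  # a 0.99 equicorrelation block is recovered within sampling error
  cfg <- table_gen_config(n_e = 400, n_ne = 400, seed = 5)
  big <- generate_feature_table(cfg)
  R <- feature_correlations(big, cfg$cor_features)
  off <- R[upper.tri(R)]
  expect_true(all(abs(off - 0.99) < 0.01))

  # zero-variance features are flagged
  tab$energy <- 1
  R <- feature_correlations(tab, c("autocorrelation", "energy"))
  expect_equal(attr(R, "zero_variance"), "energy")
  expect_true(is.na(R["autocorrelation", "energy"]))
})

test_that("power curve is exact under the null, monotone, and matches power.t.test", {
  # null case: power equals alpha for every n
  pc <- power_curve(0, sd = 1, alpha = 0.07, n_per_group = c(5, 20, 80))
  expect_equal(pc$power, rep(0.07, 3), tolerance = 1e-12)

  # monotone in n and in effect, consistent as n grows
  pc <- power_curve(0.5, sd = 1, n_per_group = c(5, 10, 25, 50, 100, 400))
  expect_true(all(diff(pc$power) > 0))
  expect_gt(tail(pc$power, 1), 0.999)
  p_small <- power_curve(0.3, 1, n_per_group = 40)$power
  p_large <- power_curve(0.8, 1, n_per_group = 40)$power
  expect_gt(p_large, p_small)

  # agrees with the independent stats::power.t.test implementation
  for (n in c(10, 50, 100)) {
    mine <- power_curve(23, sd = 35.19, n_per_group = n)$power
    ref <- stats::power.t.test(n = n, delta = 23, sd = 35.19, strict = TRUE)$power
    expect_equal(mine, ref, tolerance = 1e-6)
  }

  # at the discriminating-feature effect size, n = 100 per group saturates
  expect_gte(power_curve(23, sd = 35.19, n_per_group = 100)$power, 0.99)

  expect_error(power_curve(1, 1, alpha = 1.2), "alpha")
  expect_error(power_curve(1, 0), "sd")
})

test_that("univariate table mirrors per-feature group summaries", {
  set.seed(14)
  tab <- planted_table(20, 25, shift = 3, planted = "sum_variance")
  u <- univariate_table(tab)
  expect_equal(nrow(u), 20)
  row <- u[u$feature == "sum_variance", ]
  expect_lt(row$p_value, 1e-6)
  expect_equal(row$mean_e, mean(tab$sum_variance[tab$label == "E"]))
  # most null features stay non-significant
  expect_gt(sum(u$p_value > 0.05), 10)
})
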