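test_that("rmse matches trivial and brute-force cases", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(2, 1), c(1, 2)), 1)
  withr::with_seed(51, {
    p <- rnorm(40); m <- rnorm(40)
    acc <- 0
    for (i in 1:40) acc <- acc + (p[i] - m[i])^2
    expect_equal(rmse(p, m), sqrt(acc / 40), tolerance = 1e-14)
  })
  expect_error(rmse(1:3, 1:4), "equal-length")
})

test_that("Bland-Altman bias and limits follow mean and sd of differences", {
  x <- c(4.1, 4.5, 3.9, 5.0)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  expect_equal(ba0$n_outside, 0)

  ba1 <- bland_altman(x + 1, x)  # constant difference, zero variance
  expect_equal(ba1$bias, 1)
  expect_equal(c(ba1$loa_low, ba1$loa_high), c(1, 1))

  withr::with_seed(52, {
    est <- rnorm(30, 5); mea <- rnorm(30, 5)
    ba <- bland_altman(est, mea)
    d <- est - mea
    expect_equal(ba$bias, mean(d))
    expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))

    # shift equivariance: adding c to estimated shifts bias and both limits
    ba_c <- bland_altman(est + 0.7, mea)
    expect_equal(ba_c$bias, ba$bias + 0.7)
    expect_equal(ba_c$loa_low, ba$loa_low + 0.7)
    expect_equal(ba_c$loa_high, ba$loa_high + 0.7)

    # RMSE dominates |bias| for any paired data
    expect_gte(rmse(est, mea), abs(ba$bias))
  })
  expect_error(bland_altman(1, 1), "two pairs")
})

test_that("t statistics from summaries reproduce the published group comparisons", {
  # age: training pooled from sex strata vs validation {34, 25, 20, 21}
  age_train <- pool_summaries(group_summary(n = 4, mean = 25.00, sd = 5.94),
                              group_summary(n = 4, mean = 22.25, sd = 3.95))
  age <- independent_t(age_train, group_summary(c(34, 25, 20, 21)), "pooled")
  expect_equal(age$t, -0.417, tolerance = 0.0005)
  expect_equal(age$df, 10)

  mass_train <- pool_summaries(group_summary(n = 4, mean = 74.72, sd = 14.73),
                               group_summary(n = 4, mean = 64.30, sd = 9.32))
  mass <- independent_t(mass_train,
                        group_summary(c(90.58, 59.25, 68.72, 67.28)), "pooled")
  expect_equal(mass$t, -0.245, tolerance = 0.005)
  expect_equal(mass$df, 10)
})

test_that("t statistic agrees with t.test and is antisymmetric", {
  withr::with_seed(53, {
    a <- rnorm(8, 10, 2); b <- rnorm(6, 11, 3)
    ours <- independent_t(a, b, "pooled")
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter))

    ours_w <- independent_t(a, b, "welch")
    ref_w <- t.test(a, b)
    expect_equal(ours_w$t, unname(ref_w$statistic), tolerance = 1e-12)
    expect_equal(ours_w$df, unname(ref_w$parameter), tolerance = 1e-10)

    # antisymmetry
    flip <- independent_t(b, a, "pooled")
    expect_equal(flip$t, -ours$t)
    expect_equal(flip$df, ours$df)
  })

  # identical groups: t defined as 0 even with zero variance
  same <- group_summary(n = 4, mean = 5, sd = 0)
  expect_equal(independent_t(same, same, "pooled")$t, 0)
})

test_that("group screening recommends pooled vs Welch from Levene's test", {
  withr::with_seed(54, {
    x <- rnorm(20)
    scr <- group_screen(list(a = x, b = x + 0.1))
    expect_equal(scr$recommendation, "pooled")
    expect_true(all(scr$shapiro_p > 0))

    # constructed heteroscedasticity: one group scaled by 100
    scr2 <- group_screen(list(a = x, b = 100 * x))
    expect_equal(scr2$recommendation, "welch")
    expect_lt(scr2$levene_p, 0.05)

    expect_warning(group_screen(list(a = c(1, 2), b = rnorm(10))),
                   "fewer than 3")
  })
})
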