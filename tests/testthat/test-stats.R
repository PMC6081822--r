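test_that("paired t-test reproduces the closed-form worked example", {
  r <- paired_t_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r$mean_difference, 2)
  expect_equal(r$sd_difference, 1)
  expect_equal(r$t_statistic, 2 * sqrt(3), tolerance = 1e-4)
  expect_equal(r$degrees_freedom, 2)
  expect_equal(r$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-10)
  expect_equal(round(r$p_value, 4), 0.0742)

  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_error(paired_t_test(x, x), "zero variance")
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("regression handles exact, null, and degenerate cases", {
  x <- c(0, 1, 2, 3.5)
  r <- linear_regression(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)

  r0 <- linear_regression(c(0, 1, 2), c(0, 1, 0))
  expect_equal(r0$slope, 0)
  expect_equal(r0$r_squared, 0)

  expect_error(linear_regression(rep(2, 4), 1:4), "constant")
  expect_error(linear_regression(1, 1), "at least 2")
})

test_that("Bland-Altman uses 1.96 sample-sd limits and flags outliers", {
  r <- bland_altman(c(0, 0), c(1, 3))
  expect_equal(r$mean_difference, 2)
  expect_equal(r$sd_difference, sqrt(2), tolerance = 1e-5)
  expect_equal(r$lower_limit, 2 - 1.96 * sqrt(2), tolerance = 1e-5)
  expect_equal(round(r$lower_limit, 5), -0.77186)
  expect_equal(round(r$upper_limit, 5), 4.77186)
  expect_false(any(r$outlier))

  x <- c(1, 2, 3)
  same <- bland_altman(x, x)
  expect_equal(same$mean_difference, 0)
  expect_equal(c(same$lower_limit, same$upper_limit), c(0, 0))
  expect_false(any(same$outlier))

  bias <- bland_altman(x, x + 2)
  expect_equal(bias$mean_difference, 2)
  expect_equal(c(bias$lower_limit, bias$upper_limit), c(2, 2))

  out <- bland_altman(c(rep(0, 9), 0), c(rnorm(9, 0, 0.1), 50))
  expect_true(out$outlier[10])
})

test_that("all three statistics match first-principles formulas", {
  withr::local_seed(99)
  for (i in 1:8) {
    n <- sample(3:12, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)

    d <- y - x
    tt <- paired_t_test(x, y)
    t_manual <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(tt$t_statistic, t_manual, tolerance = 1e-10)
    expect_equal(tt$p_value, 2 * pt(-abs(t_manual), n - 1), tolerance = 1e-10)

    fit <- linear_regression(x, y)
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    ic <- mean(y) - sl * mean(x)
    res <- y - ic - sl * x
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    se_sl <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
    expect_equal(fit$slope, sl, tolerance = 1e-10)
    expect_equal(fit$intercept, ic, tolerance = 1e-10)
    expect_equal(fit$r_squared, r2, tolerance = 1e-10)
    expect_equal(fit$p_value, 2 * pt(-abs(sl / se_sl), n - 2), tolerance = 1e-10)

    ba <- bland_altman(x, y)
    expect_equal(ba$mean_difference, mean(d), tolerance = 1e-12)
    expect_equal(ba$lower_limit, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
    expect_equal(ba$upper_limit, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  }
})

test_that("statistics obey symmetry and invariance properties", {
  withr::local_seed(5)
  x <- rnorm(9)
  y <- rnorm(9, 0.4)
  a <- paired_t_test(x, y)
  b <- paired_t_test(y, x)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_value, b$p_value)

  f1 <- linear_regression(x, y)
  f2 <- linear_regression(x, 3.2 * y + 7)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)
})

test_that("tidy and glance methods return one-row summaries", {
  x <- c(1, 2, 3, 4)
  y <- c(1.2, 2.1, 3.4, 3.9)
  expect_named(glance(paired_t_test(x, y)),
               c("estimate", "statistic", "p.value", "parameter",
                 "sd.difference", "n"))
  g <- glance(linear_regression(x, y))
  expect_equal(g$n, 4)
  ba <- bland_altman(x, y)
  expect_equal(nrow(tidy(ba)), 4)
  expect_s3_class(autoplot(ba), "ggplot")
  expect_s3_class(autoplot(linear_regression(x, y)), "ggplot")
})
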