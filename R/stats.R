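#' Paired-sample t-test
#'
#' Two-sided paired t-test on the differences `y - x`, the primary test used
#' to compare SD and SS measurements of the same eyes. Sample (n-1) standard
#' deviations throughout; no multiple-testing correction is applied by
#' default, matching the analysis this package reproduces (a Bonferroni
#' adjustment can be applied downstream via [stats::p.adjust()]).
#'
#' @param x,y Equal-length numeric vectors of paired measurements.
#' @return A `paired_t_result`: `n`, `mean_difference`, `sd_difference`,
#'   `t_statistic`, `degrees_freedom`, `p_value`. Supports [tidy()] and
#'   [glance()].
#' @export
#' @examples
#' paired_t_test(c(1, 2, 3, 4), c(2, 4, 5, 5))
paired_t_test <- function(x, y) {
  check_paired(x, y)
  d <- y - x
  if (length(d) < 2L) abort("Paired t-test needs at least 2 pairs.")
  sdd <- sd(d)
  if (!is.finite(sdd) || sdd == 0) {
    abort("Differences have zero variance; the paired t-test is degenerate.")
  }
  ht <- t.test(y, x, paired = TRUE)
  structure(
    list(n = length(d),
         mean_difference = mean(d),
         sd_difference = sdd,
         t_statistic = unname(ht$statistic),
         degrees_freedom = unname(ht$parameter),
         p_value = ht$p.value),
    class = "paired_t_result"
  )
}

#' Ordinary least-squares regression of y on x
#'
#' Simple linear regression with the slope's two-sided t-test (df = n - 2)
#' and the coefficient of determination, used for the inter-device CSV
#' agreement and the signal-difference-versus-CSV analyses.
#'
#' @param x,y Numeric vectors of equal length; `x` must not be constant.
#' @return An `ols_result`: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' linear_regression(1:5, c(1.1, 2.9, 5.2, 7.1, 8.8))
linear_regression <- function(x, y) {
  check_paired(x, y)
  n <- length(x)
  if (n < 2L) abort("Regression needs at least 2 points.")
  if (sd(x) == 0) abort("`x` is constant; the regression slope is undefined.")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # silences the "perfect fit" note
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else sm$r.squared
  p <- if (n >= 3L) unname(sm$coefficients["x", "Pr(>|t|)"]) else NA_real_
  structure(
    list(slope = unname(coef(fit)[["x"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r_squared = r2,
         p_value = p,
         n = n,
         data = tibble(x = x, y = y)),
    class = "ols_result"
  )
}

#' Bland-Altman agreement analysis
#'
#' Agreement between two measurement methods via the differences
#' `d = y - x`: the mean difference (bias), the sample standard deviation of
#' the differences, and the 95% limits of agreement `mean +/- 1.96 * sd`
#' (exactly 1.96, not a t quantile). Pairs falling outside the limits are
#' flagged as outliers.
#'
#' @param x,y Equal-length numeric vectors of paired measurements.
#' @return A `bland_altman_result`: `n`, `mean_difference`, `sd_difference`,
#'   `lower_limit`, `upper_limit`, `outlier` (logical per pair). Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' bland_altman(c(1, 2, 3), c(1.2, 1.9, 3.3))
bland_altman <- function(x, y) {
  check_paired(x, y)
  if (length(x) < 2L) abort("Bland-Altman analysis needs at least 2 pairs.")
  d <- y - x
  m <- mean(d)
  s <- sd(d)
  lower <- m - 1.96 * s
  upper <- m + 1.96 * s
  structure(
    list(n = length(d),
         mean_difference = m,
         sd_difference = s,
         lower_limit = lower,
         upper_limit = upper,
         outlier = d < lower | d > upper,
         data = tibble(mean_pair = (x + y) / 2, difference = d)),
    class = "bland_altman_result"
  )
}

check_paired <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) abort("`x` and `y` must be numeric.")
  if (length(x) != length(y)) {
    abort(sprintf("`x` (%d) and `y` (%d) must have equal length.",
                  length(x), length(y)))
  }
  if (anyNA(x) || anyNA(y)) abort("Missing values are not supported.")
  invisible(TRUE)
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: n = %d, mean diff = %.4g (sd %.4g), t(%d) = %.4g, p = %.4g\n",
    x$n, x$mean_difference, x$sd_difference, x$degrees_freedom,
    x$t_statistic, x$p_value
  ))
  invisible(x)
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf(
    "OLS: y = %.4g x + %.4g, R^2 = %.4g, slope p = %.4g, n = %d\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: n = %d, bias = %.4g, LoA [%.4g, %.4g], %d outlier(s)\n",
    x$n, x$mean_difference, x$lower_limit, x$upper_limit, sum(x$outlier)
  ))
  invisible(x)
}

#' @export
tidy.paired_t_result <- function(x, ...) {
  tibble(estimate = x$mean_difference, statistic = x$t_statistic,
         p.value = x$p_value, parameter = x$degrees_freedom,
         sd.difference = x$sd_difference, n = x$n)
}

#' @export
glance.paired_t_result <- function(x, ...) tidy(x)

#' @export
tidy.ols_result <- function(x, ...) {
  tibble(term = c("(Intercept)", "x"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.ols_result <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p_value,
         slope = x$slope, intercept = x$intercept, n = x$n)
}

#' @export
tidy.bland_altman_result <- function(x, ...) {
  dplyr::mutate(x$data, outlier = x$outlier)
}

#' @export
glance.bland_altman_result <- function(x, ...) {
  tibble(mean_difference = x$mean_difference,
         sd_difference = x$sd_difference,
         lower_limit = x$lower_limit, upper_limit = x$upper_limit,
         n_outliers = sum(x$outlier), n = x$n)
}

#' @export
autoplot.bland_altman_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_pair, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = object$mean_difference, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$lower_limit, object$upper_limit),
                        linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "Mean of paired measurements", y = "Difference (y - x)",
                  title = "Bland-Altman agreement",
                  subtitle = sprintf("bias %.3g, 95%% LoA [%.3g, %.3g]",
                                     object$mean_difference, object$lower_limit,
                                     object$upper_limit))
}

#' @export
autoplot.ols_result <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::labs(title = "Linear regression",
                  subtitle = sprintf("slope %.3g, R² = %.3f, p = %.3g",
                                     object$slope, object$r_squared, object$p_value))
}
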