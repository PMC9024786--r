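# Correlation and agreement statistics.

#' Pearson correlation with coefficient of determination
#'
#' Pearson r, R^2, the ordinary least-squares slope and intercept of y on x,
#' and the two-sided p-value from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.  Pairs
#' with a missing member are dropped.
#'
#' @param x,y paired numeric vectors, n >= 3 after NA removal, each with
#'   nonzero variance.
#' @return A list of class `correlation_result`: `n`, `r`, `r_squared`,
#'   `p_value`, `slope`, `intercept`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 complete pairs, got %d", n)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("correlation undefined: zero variance")
  r <- stats::cor(x, y)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(n = n, r = r, r_squared = r^2, p_value = p,
                 slope = slope, intercept = intercept),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("R^2 = %.3f, p = %.3g (n = %d; y = %.3g + %.3g x)\n",
              x$r_squared, x$p_value, x$n, x$intercept, x$slope))
  invisible(x)
}

#' Mean difference between paired measurements
#'
#' Agreement statistics of `a - b` (Bland-Altman style mean difference and
#' SD of differences).
#'
#' @param a,b paired numeric vectors of equal length, n >= 2 after dropping
#'   incomplete pairs.
#' @return A list of class `agreement_result`: `n`, `mean_difference`,
#'   `sd_difference`.
#' @export
mean_difference <- function(a, b) {
  if (length(a) != length(b)) stopf("a and b must have equal length")
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  if (length(d) < 2) stopf("need at least 2 complete pairs")
  structure(list(n = length(d), mean_difference = mean(d),
                 sd_difference = stats::sd(d)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("mean difference = %.3g +/- %.3g (n = %d)\n",
              x$mean_difference, x$sd_difference, x$n))
  invisible(x)
}
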