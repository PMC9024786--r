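# Segmented (hinge) regression with an exhaustive grid search on the
# breakpoint.

#' Fit a continuous two-segment (biphasic) linear model
#'
#' Fits `y = a + b1 * min(x - c, 0) + b2 * max(x - c, 0)` - a continuous
#' piecewise-linear ("hinge") model - by exhaustive grid search on the
#' breakpoint `c` over the interior 10-90 percent quantile range of `x` in
#' steps of `grid_step`, solving ordinary least squares at each candidate
#' and keeping the smallest sum of squared errors (ties keep the smallest
#' breakpoint, deterministically).  Candidates leaving fewer than three
#' points on either side are skipped.  The single-line SSE is reported for
#' comparison; when the hinge improves on it by less than one percent the
#' breakpoint is flagged unstable.
#'
#' @param x,y paired numeric vectors (n >= 6 complete pairs).
#' @param grid_step breakpoint grid step, in units of `x` (um for the
#'   imaging biomarkers).
#' @return An object of class `biphasic_fit`: `breakpoint`, `slope_below`,
#'   `slope_above`, `intercept` (fitted value at the breakpoint),
#'   `sse_piecewise`, `sse_linear`, `n`, `unstable`, plus the data and grid
#'   for the methods.
#' @seealso [predict.biphasic_fit()], [plot.biphasic_fit()]
#' @export
fit_biphasic <- function(x, y, grid_step = 25) {
  if (length(x) != length(y)) stopf("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 6) stopf("need at least 6 complete pairs, got %d", n)
  qs <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  grid <- seq(qs[1], qs[2], by = grid_step)
  if (!length(grid)) grid <- mean(qs)

  fit_at <- function(cc) {
    X <- cbind(1, pmin(x - cc, 0), pmax(x - cc, 0))
    if (sum(x < cc) < 3 || sum(x > cc) < 3) return(NULL)
    f <- stats::lm.fit(X, y)
    list(sse = sum(f$residuals^2), coef = f$coefficients)
  }
  fits <- lapply(grid, fit_at)
  valid <- !vapply(fits, is.null, logical(1))
  if (!any(valid))
    stopf("no valid breakpoint candidate (fewer than 3 points per segment)")
  sses <- vapply(fits[valid], `[[`, numeric(1), "sse")
  best_i <- which(valid)[which.min(sses)]  # ties: smallest breakpoint
  best <- fits[[best_i]]

  lin <- stats::lm.fit(cbind(1, x), y)
  sse_lin <- sum(lin$residuals^2)

  structure(list(
    breakpoint = grid[best_i],
    slope_below = unname(best$coef[2]),
    slope_above = unname(best$coef[3]),
    intercept = unname(best$coef[1]),
    sse_piecewise = best$sse,
    sse_linear = sse_lin,
    unstable = (sse_lin - best$sse) <=
      0.01 * sse_lin + 1e-12 * sum((y - mean(y))^2),
    n = n,
    grid = grid[valid],
    grid_sse = sses,
    x = x, y = y,
    call = match.call()
  ), class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat("Biphasic (hinge) linear fit\n")
  cat(sprintf("  breakpoint : %.6g%s\n", x$breakpoint,
              if (x$unstable) "  (unstable: <1% SSE improvement over a line)"
              else ""))
  cat(sprintf("  slope below: %.6g\n  slope above: %.6g\n", x$slope_below,
              x$slope_above))
  cat(sprintf("  value at breakpoint: %.6g\n", x$intercept))
  cat(sprintf("  SSE %.6g (piecewise) vs %.6g (single line), n = %d\n",
              x$sse_piecewise, x$sse_linear, x$n))
  invisible(x)
}

#' @export
coef.biphasic_fit <- function(object, ...) {
  c(breakpoint = object$breakpoint, intercept = object$intercept,
    slope_below = object$slope_below, slope_above = object$slope_above)
}

#' Predict from a biphasic fit
#'
#' @param object a [fit_biphasic()] result.
#' @param newdata numeric vector of x values; defaults to the training x.
#' @param ... unused.
#' @return fitted values.
#' @export
predict.biphasic_fit <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x else newdata
  object$intercept + object$slope_below * pmin(xx - object$breakpoint, 0) +
    object$slope_above * pmax(xx - object$breakpoint, 0)
}

#' @export
residuals.biphasic_fit <- function(object, ...) {
  object$y - predict(object)
}

#' Plot a biphasic fit
#'
#' Scatter of the data with the fitted hinge model and breakpoint marked.
#'
#' @param x a [fit_biphasic()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.biphasic_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), lwd = 2)
  graphics::abline(v = x$breakpoint, lty = 2)
  invisible(x)
}
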