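# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Smooth step: 0 well inside r0, 1 well outside, transition width `sigma`
# (Gaussian edge profile).  sigma <= 0 degenerates to a hard step.
# Preserves the dim attribute of matrix input.
smooth_step <- function(r, r0, sigma) {
  if (sigma <= 0) return((r > r0) * 1)
  stats::pnorm((r - r0) / sigma)
}

# Gaussian smoothing of a 1-D signal with reflective edge handling.
# sigma is in samples; sigma <= 0 returns the input unchanged.
gauss_smooth_1d <- function(y, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  pad <- c(y[pmin(half:1, n)], y, y[pmax(n - (1:half) + 1, 1)])
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# Robust noise-level estimate from first differences of a signal.
noise_sd_estimate <- function(y) {
  d <- diff(y)
  if (length(d) < 2) return(0)
  stats::mad(d, center = 0) / sqrt(2)
}

# Linear interpolation of the position where `y` crosses `level` between
# consecutive samples i and i+1 (assumes y[i], y[i+1] bracket the level).
interp_crossing <- function(x, y, i, level) {
  if (y[i + 1] == y[i]) return(x[i])
  x[i] + (level - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
}
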