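# OCT B-scan analysis: display-to-linear transform, band-width calipers and
# the longitudinal reflectivity profile with normalised EZ reflectance.

#' Invert the OCT display transform
#'
#' The stored B-scan is a power-law display compression of the linear
#' reflectance; this inverts it, `I_lin` proportional to `I_disp^gamma`,
#' normalised to \[0, 1\].  Applying it to an already linear scan is an
#' error so the transform can never be silently applied twice.
#'
#' @param scan a [retina_image] with `scale_flag = "log"`.
#' @param gamma display exponent (>= 1), matching the acquisition transform.
#' @return the linear-scale [retina_image] (`scale_flag = "linear"`).
#' @export
log_to_linear <- function(scan, gamma = 4) {
  stopifnot(inherits(scan, "retina_image"))
  if (scan$scale_flag != "log")
    stopf("scan is already on a linear scale")
  if (gamma < 1) stopf("gamma must be >= 1")
  lin <- scan$grid^gamma
  mx <- max(lin)
  if (mx > 0) lin <- lin / mx
  out <- scan
  out$grid <- lin
  out$scale_flag <- "linear"
  out
}

#' Measure intact EZ and ELM band widths
#'
#' For each band, the per-column intensity is the maximum over the depth
#' window `hint +/- 3 * band sigma`.  A column is "present" when it exceeds
#' the background reference (the same column-maximum statistic computed in
#' the vitreous above the retina) by two background SDs.  The band width is
#' the lateral extent of the maximal present run containing the foveal
#' column, tolerating gaps up to `gap_tolerance_um`; a run touching the scan
#' edge is flagged `exceeds_window` (its width is then a lower bound).
#'
#' @param scan a linear-scale OCT [retina_image].
#' @param band_depth_hints_um named vector of band centre depths, must
#'   include `EZ` and `ELM` (um); by default from [render_config()].
#' @param band_sigma_um named vector of band axial widths (um).
#' @param gap_tolerance_um largest lateral gap bridged within a run (um).
#' @return A list of class `band_widths` with `ez_width`, `elm_width` (um)
#'   and per-band `flags` (`"contained"` or `"exceeds_window"`).
#' @export
measure_band_widths <- function(scan,
                                band_depth_hints_um =
                                  render_config()$oct_band_depth_um,
                                band_sigma_um =
                                  render_config()$oct_band_sigma_um,
                                gap_tolerance_um = 50) {
  stopifnot(inherits(scan, "retina_image"))
  if (scan$scale_flag != "linear")
    stopf("band widths are measured on the linear-scale scan")
  z <- axial_axis_um(scan)
  fov_col <- round(scan$fovea[["x"]])
  gap_px <- max(0L, floor(gap_tolerance_um / scan$pixel_scale))

  band_width_one <- function(band) {
    hint <- band_depth_hints_um[[band]]
    sig <- band_sigma_um[[band]]
    rows <- which(z >= hint - 3 * sig & z <= hint + 3 * sig)
    if (!length(rows)) stopf("depth hint for %s outside the scan", band)
    colmax <- apply(scan$grid[rows, , drop = FALSE], 2, max)
    # background: same column-maximum statistic in the vitreous above RNFL
    vit_top <- min(band_depth_hints_um) - 3 * max(band_sigma_um)
    vit_rows <- which(z < vit_top)
    if (length(vit_rows) < 3)
      stopf("no vitreous region above the retina for background statistics")
    vit_rows <- utils::tail(vit_rows, length(rows))
    bg <- apply(scan$grid[vit_rows, , drop = FALSE], 2, max)
    # floor at 1% of the band's dynamic range: keeps the threshold
    # meaningful when the background SD collapses (noiseless limit) and
    # rejects axial tails of neighbouring bands leaking into the window
    thr <- mean(bg) + max(2 * stats::sd(bg),
                          0.01 * (max(colmax) - mean(bg)))
    present <- colmax > thr
    # a single isolated supra-threshold column is speckle, not band: require
    # presence segments of at least two adjacent columns before bridging gaps
    n_p <- length(present)
    isolated <- present &
      !(c(FALSE, present[-n_p]) | c(present[-1], FALSE))
    present[isolated] <- FALSE
    if (!present[fov_col]) {
      warnf("%s band absent at the foveal column; width 0", band)
      return(list(width = 0, flag = "contained"))
    }
    # grow the run from the fovea, bridging gaps <= gap_px
    lo <- fov_col
    gap <- 0L
    i <- fov_col
    while (i > 1) {
      i <- i - 1L
      if (present[i]) { lo <- i; gap <- 0L } else {
        gap <- gap + 1L
        if (gap > gap_px) break
      }
    }
    hi <- fov_col
    gap <- 0L
    i <- fov_col
    n <- length(present)
    while (i < n) {
      i <- i + 1L
      if (present[i]) { hi <- i; gap <- 0L } else {
        gap <- gap + 1L
        if (gap > gap_px) break
      }
    }
    flag <- if (lo <= 1L || hi >= n) "exceeds_window" else "contained"
    list(width = (hi - lo + 1L) * scan$pixel_scale, flag = flag)
  }

  ez <- band_width_one("EZ")
  elm <- band_width_one("ELM")
  structure(list(ez_width = ez$width, elm_width = elm$width,
                 flags = c(EZ = ez$flag, ELM = elm$flag)),
            class = "band_widths")
}

#' @export
print.band_widths <- function(x, ...) {
  cat(sprintf("<band_widths> EZ = %.0f um [%s]  ELM = %.0f um [%s]\n",
              x$ez_width, x$flags[["EZ"]], x$elm_width, x$flags[["ELM"]]))
  invisible(x)
}

#' Longitudinal reflectivity profile
#'
#' Per-depth mean reflectance over all columns within half the window width
#' of the foveal column (default: a 1000-um window centred at the foveal
#' pit).
#'
#' @param scan a linear-scale OCT [retina_image].
#' @param window_um lateral window width (um).
#' @return A list of class `lr_profile` with `depth_um`, `reflectance`,
#'   `window_um` and (after [identify_layer_peaks()]) `peaks`.
#' @export
longitudinal_reflectivity_profile <- function(scan, window_um = 1000) {
  stopifnot(inherits(scan, "retina_image"))
  if (scan$scale_flag != "linear")
    stopf("the LRP is computed on the linear-scale scan")
  x <- lateral_axis_um(scan)
  sel <- abs(x) <= window_um / 2
  if (min(x) > -window_um / 2 || max(x) < window_um / 2)
    stopf("%.0f-um window exceeds the scan width", window_um)
  structure(list(depth_um = axial_axis_um(scan),
                 reflectance = rowMeans(scan$grid[, sel, drop = FALSE]),
                 window_um = window_um, peaks = NULL),
            class = "lr_profile")
}

# indices of local maxima of y (plateaus contribute their deepest sample)
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (j in seq_len(k)) {
    left_ok <- j == 1 || r$values[j - 1] < r$values[j]
    right_ok <- j == k || r$values[j + 1] < r$values[j]
    if (left_ok && right_ok && !(j == 1 || j == k))
      out <- c(out, ends[j])  # deepest sample of a plateau
  }
  out
}

#' Identify and label the six layer peaks of an LRP
#'
#' Takes the six most prominent local maxima of the profile (prominence =
#' peak height minus the higher of the two adjacent troughs) and labels them
#' in depth order RNFL, INL, ELM, EZ, IZ, RPE.  Ties in prominence keep the
#' deeper peak, deterministically.  Fewer than six maxima above the noise
#' floor is an error reporting the count found - the signature of advanced
#' degeneration (a band lost from the window) or bad input.
#'
#' @param lrp a [longitudinal_reflectivity_profile()] result.
#' @return the `lr_profile` with `peaks`: a named integer vector of profile
#'   indices.
#' @export
identify_layer_peaks <- function(lrp) {
  stopifnot(inherits(lrp, "lr_profile"))
  y <- lrp$reflectance
  noise_floor <- noise_sd_estimate(y)
  cand <- .local_maxima(y)
  if (length(cand)) {
    prom <- vapply(cand, function(i) {
      others <- cand[cand != i]
      left <- others[others < i]
      right <- others[others > i]
      tl <- min(y[seq(if (length(left)) max(left) else 1, i)])
      tr <- min(y[seq(i, if (length(right)) min(right) else length(y))])
      y[i] - max(tl, tr)
    }, numeric(1))
    keep <- prom > 3 * noise_floor
    cand <- cand[keep]; prom <- prom[keep]
  }
  if (length(cand) < 6)
    stopf("found %d layer peak(s), need 6", length(cand))
  ord <- order(-prom, -cand)  # prominence desc; ties keep the deeper peak
  six <- sort(cand[ord[1:6]])
  names(six) <- c("RNFL", "INL", "ELM", "EZ", "IZ", "RPE")
  lrp$peaks <- six
  lrp$prominence <- prom[match(six, cand)]
  names(lrp$prominence) <- names(six)
  lrp
}

#' Normalised EZ reflectance from a labelled LRP
#'
#' Mean reflectance over the EZ peak's full-width-at-half-prominence depth
#' band divided by the mean reflectance over the closed depth span from the
#' RNFL peak to the INL peak.  Invariant to global linear intensity scaling.
#'
#' @param lrp an [identify_layer_peaks()] result.
#' @return the dimensionless reflectance ratio.
#' @export
normalized_ez_reflectance <- function(lrp) {
  stopifnot(inherits(lrp, "lr_profile"))
  if (is.null(lrp$peaks)) stopf("label the layer peaks first")
  y <- lrp$reflectance
  i_ez <- lrp$peaks[["EZ"]]
  half <- y[i_ez] - 0.5 * lrp$prominence[["EZ"]]
  lo <- i_ez
  while (lo > 1 && y[lo - 1] >= half) lo <- lo - 1
  hi <- i_ez
  while (hi < length(y) && y[hi + 1] >= half) hi <- hi + 1
  num <- mean(y[lo:hi])
  den_span <- lrp$peaks[["RNFL"]]:lrp$peaks[["INL"]]
  den <- mean(y[den_span])
  if (den <= 3 * noise_sd_estimate(y))
    stopf("inner retinal reflectance at the noise floor; ratio undefined")
  num / den
}
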