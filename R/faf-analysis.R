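# FAF ring-diameter measurement: horizontal caliper on the intensity
# profile through the fovea.

#' Horizontal intensity profile through the fovea
#'
#' Mean of the image rows within `band_halfwidth_um` of the foveal row,
#' indexed by signed lateral distance from the fovea in micrometres.  A band
#' narrower than one pixel degenerates to the single foveal row with a
#' warning.
#'
#' @param image a [retina_image].
#' @param band_halfwidth_um half-width of the averaging band (um).
#' @return A list of class `lateral_profile` with elements `x_um`,
#'   `intensity` and `pixel_scale`.
#' @export
horizontal_profile <- function(image, band_halfwidth_um = 25) {
  stopifnot(inherits(image, "retina_image"))
  fy <- image$fovea[["y"]]
  half_px <- floor(band_halfwidth_um / image$pixel_scale)
  if (half_px < 1 && band_halfwidth_um < image$pixel_scale)
    warnf("averaging band narrower than one pixel; using the foveal row only")
  rows <- max(1, round(fy) - half_px):min(nrow(image$grid), round(fy) + half_px)
  prof <- colMeans(image$grid[rows, , drop = FALSE])
  structure(list(x_um = lateral_axis_um(image), intensity = prof,
                 pixel_scale = image$pixel_scale),
            class = "lateral_profile")
}

# one side of the ring measurement; x, y restricted to that side with x
# increasing away from the fovea (positive distances).
.measure_side <- function(x, y, exclusion_um, noise_sd,
                          criterion = "half_height") {
  sel <- x > exclusion_um
  if (!any(sel)) return(list(flag = "no_ring"))
  peak_i_rel <- which.max(y[sel])
  peak_i <- which(sel)[peak_i_rel]
  peak <- y[peak_i]
  n_side <- length(x)
  base_n <- max(3L, ceiling(0.1 * n_side))
  baseline <- stats::median(y[(n_side - base_n + 1):n_side])
  trough <- min(y[x <= x[peak_i]])
  if (peak <= baseline + 2 * noise_sd || peak <= trough + 2 * noise_sd)
    return(list(flag = "no_ring"))

  if (criterion == "gradient") {
    # steepest rise on the inner flank, steepest fall on the outer flank
    g <- diff(y) / diff(x)
    trough_i <- which.min(y[x <= x[peak_i]])
    inner <- if (trough_i >= peak_i) NA_real_ else {
      k <- trough_i + which.max(g[trough_i:(peak_i - 1)]) - 1L
      (x[k] + x[k + 1]) / 2
    }
    if (peak_i >= n_side)
      return(list(flag = "truncated", inner = inner, outer = NA_real_,
                  peak_x = x[peak_i]))
    k <- peak_i + which.min(g[peak_i:(n_side - 1)]) - 1L
    outer <- (x[k] + x[k + 1]) / 2
    if (k >= n_side - 1)
      return(list(flag = "truncated", inner = inner, outer = outer,
                  peak_x = x[peak_i]))
    return(list(flag = "ok", inner = inner, outer = outer,
                peak_x = x[peak_i]))
  }

  # inner border: half-height crossing between the central trough and peak
  half_in <- trough + 0.5 * (peak - trough)
  i <- peak_i
  while (i > 1 && y[i - 1] >= half_in) i <- i - 1
  inner <- if (i == 1) NA_real_ else interp_crossing(x, y, i - 1, half_in)

  # outer border: half-height crossing between the peak and the baseline
  half_out <- baseline + 0.5 * (peak - baseline)
  j <- peak_i
  while (j < n_side && y[j + 1] >= half_out) j <- j + 1
  if (j == n_side)
    return(list(flag = "truncated", inner = inner, outer = NA_real_,
                peak_x = x[peak_i]))
  outer <- interp_crossing(x, y, j, half_out)
  list(flag = "ok", inner = inner, outer = outer, peak_x = x[peak_i])
}

#' Measure hyperautofluorescent ring diameters
#'
#' On each side of the fovea the ring peak is the intensity maximum outside
#' a central exclusion zone (foveal reflex protection).  The inner-ring
#' border is the half-height crossing on the inner flank (referenced to the
#' central trough), the outer-ring border the half-height crossing on the
#' outer flank (referenced to the peripheral baseline, the median of the
#' outermost 10 percent of the profile).  Diameters are right border minus
#' left border.  A side with no peak exceeding baseline + 2 noise SD yields
#' `quality_flag = "no_ring"`; a crossing that runs off the field yields
#' `"truncated"`.
#'
#' @param profile a [horizontal_profile()] result spanning the fovea.
#' @param smoothing Gaussian smoothing width applied to the profile before
#'   peak finding (um).
#' @param exclusion_um central exclusion radius (um).
#' @param criterion border criterion: `"half_height"` (default; robust to
#'   amplitude scaling) or `"gradient"` (steepest flank, for sensitivity
#'   analysis).
#' @return A list of class `ring_measurement` with `ir_diameter`,
#'   `or_diameter` (um), per-side border positions and `quality_flag`
#'   (`"ok"`, `"no_ring"` or `"truncated"`).
#' @export
measure_ring_diameters <- function(profile, smoothing = 50,
                                   exclusion_um = 200,
                                   criterion = c("half_height", "gradient")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(profile, "lateral_profile"))
  x <- profile$x_um
  if (min(x) > 0 || max(x) < 0) stopf("profile does not span the fovea")
  noise_sd <- noise_sd_estimate(profile$intensity)
  y <- gauss_smooth_1d(profile$intensity, smoothing / profile$pixel_scale)

  right <- .measure_side(x[x >= 0], y[x >= 0], exclusion_um, noise_sd,
                         criterion = criterion)
  left <- .measure_side(-rev(x[x <= 0]), rev(y[x <= 0]), exclusion_um,
                        noise_sd, criterion = criterion)
  flag <- if (identical(right$flag, "no_ring") ||
              identical(left$flag, "no_ring")) "no_ring"
          else if (identical(right$flag, "truncated") ||
                   identical(left$flag, "truncated")) "truncated"
          else "ok"
  ir <- or <- NA_real_
  borders <- list(left_inner = NA_real_, left_outer = NA_real_,
                  right_inner = NA_real_, right_outer = NA_real_)
  if (flag != "no_ring") {
    borders <- list(left_inner = -left$inner, left_outer = -left$outer,
                    right_inner = right$inner, right_outer = right$outer)
    ir <- borders$right_inner - borders$left_inner
    or <- borders$right_outer - borders$left_outer
  }
  structure(list(ir_diameter = ir, or_diameter = or, borders = borders,
                 quality_flag = flag),
            class = "ring_measurement")
}

#' @export
print.ring_measurement <- function(x, ...) {
  cat(sprintf("<ring_measurement> IR = %.0f um  OR = %.0f um  [%s]\n",
              x$ir_diameter, x$or_diameter, x$quality_flag))
  invisible(x)
}
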