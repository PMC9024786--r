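# AOSLO analysis: axial-length scaling, cone detection in sampling windows,
# modality choice, foveal cone density and intact-mosaic diameter.

#' Micrometres per degree of visual angle from axial length
#'
#' Linear schematic-eye scaling: `constant * AL / reference_al`, i.e.
#' 291 um/deg for a 24.00 mm eye by default.  Strictly increasing in axial
#' length.
#'
#' @param axial_length axial length in mm, within \[20, 30\].
#' @param constant um/deg of the reference eye.
#' @param reference_al reference axial length (mm).
#' @return micrometres per degree.
#' @examples
#' micrometres_per_degree(24)    # 291
#' micrometres_per_degree(23.88) # 289.545
#' @export
micrometres_per_degree <- function(axial_length, constant = 291,
                                   reference_al = 24) {
  if (any(axial_length < 20 | axial_length > 30))
    stopf("axial length outside the plausible range [20, 30] mm")
  constant * axial_length / reference_al
}

#' Place the two foveal cone-sampling windows
#'
#' Two square windows of side `size_um` centred on the horizontal meridian
#' at +/- `eccentricity_um` from the fovea (temporal and nasal).
#'
#' @param montage an AOSLO [retina_image].
#' @param eccentricity_um window-centre eccentricity (um).
#' @param size_um window side (um).
#' @return list of two window specs, each `list(centre_um = c(x, y),
#'   size_um)`.
#' @export
place_sampling_windows <- function(montage, eccentricity_um = 100,
                                   size_um = 100) {
  stopifnot(inherits(montage, "retina_image"))
  half_w <- (ncol(montage$grid) - montage$fovea[["x"]]) * montage$pixel_scale
  half_h <- (nrow(montage$grid) - montage$fovea[["y"]]) * montage$pixel_scale
  if (eccentricity_um + size_um / 2 > half_w || size_um / 2 > half_h ||
      eccentricity_um + size_um / 2 >
        (montage$fovea[["x"]] - 1) * montage$pixel_scale)
    stopf("sampling window falls outside the montage")
  if (2 * eccentricity_um < size_um)
    warnf("sampling windows overlap at eccentricity %.0f um", eccentricity_um)
  lapply(c(-1, 1), function(s)
    list(centre_um = c(x = s * eccentricity_um, y = 0), size_um = size_um))
}

#' Extract a window sub-image around a position
#'
#' @param montage an AOSLO [retina_image].
#' @param window a window spec from [place_sampling_windows()].
#' @param margin_um extra margin kept on every side (detection context).
#' @return A [retina_image] crop whose fovea slot holds the original foveal
#'   position in the cropped coordinates (possibly outside the crop, so it
#'   is stored as an attribute `origin_um` instead: the (x, y) of the crop's
#'   first pixel relative to the fovea, in um).
#' @export
extract_window <- function(montage, window, margin_um = 10) {
  stopifnot(inherits(montage, "retina_image"))
  sc <- montage$pixel_scale
  cx <- montage$fovea[["x"]] + window$centre_um[["x"]] / sc
  cy <- montage$fovea[["y"]] + window$centre_um[["y"]] / sc
  half <- (window$size_um / 2 + margin_um) / sc
  cols <- max(1, floor(cx - half)):min(ncol(montage$grid), ceiling(cx + half))
  rows <- max(1, floor(cy - half)):min(nrow(montage$grid), ceiling(cy + half))
  crop <- montage$grid[rows, cols, drop = FALSE]
  structure(list(grid = crop, pixel_scale = sc,
                 origin_um = c(x = (cols[1] - montage$fovea[["x"]]) * sc,
                               y = (rows[1] - montage$fovea[["y"]]) * sc),
                 window = window, modality = montage$modality),
            class = "aoslo_window")
}

# greedy non-maximum suppression with a spatial grid; keeps the brightest
# of any pair closer than min_sep
.suppress_close <- function(x, y, intensity, min_sep) {
  if (length(x) <= 1) return(seq_along(x))
  ord <- order(-intensity)
  cell <- max(min_sep, 1e-6)
  gx <- floor(x / cell); gy <- floor(y / cell)
  occupied <- new.env(hash = TRUE, size = length(x))
  keep <- logical(length(x))
  for (i in ord) {
    ok <- TRUE
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste(gx[i] + dx, gy[i] + dy)
        prev <- occupied[[key]]
        if (!is.null(prev)) {
          d2 <- (x[prev] - x[i])^2 + (y[prev] - y[i])^2
          if (any(d2 < min_sep^2)) { ok <- FALSE; break }
        }
      }
      if (!ok) break
    }
    if (ok) {
      keep[i] <- TRUE
      key <- paste(gx[i], gy[i])
      occupied[[key]] <- c(occupied[[key]], i)
    }
  }
  which(keep)
}

#' Detect cones in an AOSLO window
#'
#' Automated stand-in for manual cone identification: the window is smoothed
#' with a Gaussian kernel of width 0.4 times the expected mosaic spacing,
#' local maxima are taken with a minimum pairwise separation of 0.7 times
#' the expected spacing, and maxima must exceed the window mean plus one SD
#' of the smoothed intensity.  An empty result is allowed.
#'
#' @param window an [extract_window()] crop (or a [retina_image], in which
#'   case the whole image is searched).
#' @param expected_spacing_um expected cone spacing (um).
#' @return A `data.frame` of class `cone_set` with columns `x_um`, `y_um`
#'   (relative to the fovea) and attribute `modality`; cones inside the
#'   window proper only (the margin is search context).
#' @export
detect_cones <- function(window, expected_spacing_um) {
  if (inherits(window, "retina_image"))
    window <- structure(list(grid = window$grid,
                             pixel_scale = window$pixel_scale,
                             origin_um = c(x = (1 - window$fovea[["x"]]) *
                                             window$pixel_scale,
                                           y = (1 - window$fovea[["y"]]) *
                                             window$pixel_scale),
                             window = NULL, modality = window$modality),
                        class = "aoslo_window")
  stopifnot(inherits(window, "aoslo_window"))
  sc <- window$pixel_scale
  sigma_px <- 0.4 * expected_spacing_um / sc / 2.355  # kernel width as FWHM
  sm <- as.matrix(EBImage::gblur(window$grid, sigma = max(sigma_px, 0.5)))
  min_sep_px <- 0.7 * expected_spacing_um / sc
  brush_size <- max(3L, 2L * floor(min_sep_px / 2) + 1L)
  mx <- as.matrix(EBImage::dilate(sm, EBImage::makeBrush(brush_size, "disc")))
  thr <- mean(sm) + stats::sd(sm)
  cand <- which(sm >= mx & sm > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    out <- data.frame(x_um = numeric(0), y_um = numeric(0))
  } else {
    xs <- window$origin_um[["x"]] + (cand[, "col"] - 1) * sc
    ys <- window$origin_um[["y"]] + (cand[, "row"] - 1) * sc
    ii <- .suppress_close(xs, ys, sm[cand], min_sep_px * sc)
    out <- data.frame(x_um = xs[ii], y_um = ys[ii])
  }
  if (!is.null(window$window)) {
    cw <- window$window
    half <- cw$size_um / 2
    out <- out[abs(out$x_um - cw$centre_um[["x"]]) <= half &
                 abs(out$y_um - cw$centre_um[["y"]]) <= half, , drop = FALSE]
  }
  structure(out, class = c("cone_set", "data.frame"),
            modality = window$modality, window = window$window)
}

#' Choose the better imaging modality for a window
#'
#' The modality yielding more detectable cones wins; ties go to split
#' detection, which visualises inner segments irrespective of outer-segment
#' integrity.
#'
#' @param confocal_set,split_set [detect_cones()] results for the same
#'   window.
#' @return the chosen `cone_set`.
#' @export
choose_modality <- function(confocal_set, split_set) {
  stopifnot(inherits(confocal_set, "cone_set"), inherits(split_set, "cone_set"))
  if (nrow(confocal_set) > nrow(split_set)) confocal_set else split_set
}

#' Cone density of a detected cone set
#'
#' @param cones a `cone_set` carrying its window spec.
#' @param window_size_um window side (um); taken from the cone set's window
#'   when available.
#' @return density in cones/mm^2.
#' @export
cone_density <- function(cones, window_size_um = NULL) {
  stopifnot(inherits(cones, "cone_set"))
  if (is.null(window_size_um)) {
    w <- attr(cones, "window")
    if (is.null(w)) stopf("window size unknown; pass window_size_um")
    window_size_um <- w$size_um
  }
  if (window_size_um <= 0) stopf("window area must be positive")
  nrow(cones) / (window_size_um / 1000)^2
}

#' Foveal cone density from two sampling windows
#'
#' For each of the two windows at +/- `eccentricity_um`, cones are detected
#' on both modalities, the better modality chosen, and the window density
#' computed; the eye's foveal cone density is the mean of the two window
#' densities.
#'
#' @param confocal,split confocal and split-detection [retina_image]s of
#'   the same eye.
#' @param eccentricity_um,size_um window geometry (um).
#' @param expected_spacing_um expected cone spacing for the first detection
#'   pass (um).
#' @param adaptive when `TRUE` (default), a second detection pass per window
#'   re-uses the median nearest-neighbour distance of the first pass as the
#'   expected spacing, so the minimum-separation rule tracks the actual
#'   mosaic rather than a population prior (important in dense foveal
#'   mosaics, where a too-large separation radius merges neighbouring
#'   cones).
#' @return A list of class `density_result`: `density` (cones/mm^2) and
#'   `windows`, a per-window data frame of counts, densities and chosen
#'   modality.
#' @export
foveal_cone_density <- function(confocal, split, eccentricity_um = 100,
                                size_um = 100, expected_spacing_um = 4.5,
                                adaptive = TRUE) {
  wins <- place_sampling_windows(split, eccentricity_um, size_um)
  rows <- lapply(wins, function(w) {
    wc <- extract_window(confocal, w)
    ws <- extract_window(split, w)
    detect_both <- function(spacing) {
      cs <- detect_cones(wc, spacing)
      ss <- detect_cones(ws, spacing)
      list(cs = cs, ss = ss, chosen = choose_modality(cs, ss))
    }
    d1 <- detect_both(expected_spacing_um)
    if (adaptive && nrow(d1$chosen) >= 10) {
      s_est <- stats::median(nearest_neighbour_distances(d1$chosen))
      if (is.finite(s_est) && s_est > 0) d1 <- detect_both(s_est)
    }
    data.frame(centre_x_um = w$centre_um[["x"]],
               confocal_count = nrow(d1$cs), split_count = nrow(d1$ss),
               modality = attr(d1$chosen, "modality"),
               density = cone_density(d1$chosen))
  })
  windows <- do.call(rbind, rows)
  structure(list(density = mean(windows$density), windows = windows),
            class = "density_result")
}

#' Nearest-neighbour distances of a cone set
#'
#' @param cones a `cone_set` (or any data frame with `x_um`, `y_um`).
#' @return numeric vector of per-cone nearest-neighbour distances (um).
#' @export
nearest_neighbour_distances <- function(cones) {
  n <- nrow(cones)
  if (n < 2) return(numeric(0))
  d <- as.matrix(stats::dist(cbind(cones$x_um, cones$y_um)))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("<density_result> %.0f cones/mm^2 (windows: %s)\n", x$density,
              paste(sprintf("%.0f [%s]", x$windows$density,
                            x$windows$modality), collapse = ", ")))
  invisible(x)
}

#' Measure the intact macular photoreceptor mosaic diameter
#'
#' Cones are detected once on a horizontal strip through the fovea of the
#' split-detection montage; local density is evaluated in sliding
#' `window_size_um` square windows stepped along the meridian.  The central
#' reference density is the mean over windows centred within
#' `reference_halfwidth_um` of the fovea.  On each side, the mosaic border
#' is the innermost position where the local density falls below
#' `threshold_frac` times the reference for two consecutive windows, refined
#' by linear interpolation of the density profile through the threshold;
#' the diameter is the distance between the two borders.  If a side never
#' drops below threshold before the montage edge the result is flagged as a
#' lower bound.
#'
#' @param split a split-detection [retina_image].
#' @param window_size_um sliding window side (um).
#' @param step_um window step along the meridian (um).
#' @param threshold_frac density threshold as a fraction of the central
#'   reference.
#' @param reference_halfwidth_um half-width of the central reference zone
#'   (um).
#' @param expected_spacing_um expected cone spacing for detection (um).
#' @return A list of class `impm_measurement`: `diameter` (um), `borders`
#'   (left/right, um), `flag` (`"ok"` or `"lower_bound"`) and the sliding
#'   `profile` data frame.
#' @export
measure_impm_diameter <- function(split, window_size_um = 100, step_um = 25,
                                  threshold_frac = 0.25,
                                  reference_halfwidth_um = 300,
                                  expected_spacing_um = 4.5) {
  stopifnot(inherits(split, "retina_image"))
  strip <- list(centre_um = c(x = 0, y = 0), size_um = window_size_um)
  # full-width strip crop, window height
  sc <- split$pixel_scale
  half_rows <- floor(window_size_um / 2 / sc)
  fy <- round(split$fovea[["y"]])
  rows <- max(1, fy - half_rows):min(nrow(split$grid), fy + half_rows)
  crop <- structure(list(grid = split$grid[rows, , drop = FALSE],
                         pixel_scale = sc,
                         origin_um = c(x = (1 - split$fovea[["x"]]) * sc,
                                       y = (rows[1] - split$fovea[["y"]]) * sc),
                         window = NULL, modality = split$modality),
                    class = "aoslo_window")
  cones <- detect_cones(crop, expected_spacing_um)

  half_w <- (split$fovea[["x"]] - 1) * sc
  centres <- seq(-(half_w - window_size_um / 2),
                 half_w - window_size_um / 2, by = step_um)
  half <- window_size_um / 2
  counts <- vapply(centres, function(cx)
    sum(abs(cones$x_um - cx) <= half & abs(cones$y_um) <= half), numeric(1))
  dens <- counts / (window_size_um / 1000)^2
  profile <- data.frame(centre_x_um = centres, count = counts,
                        density = dens)

  ref_sel <- abs(centres) <= reference_halfwidth_um
  reference <- mean(dens[ref_sel])
  if (!is.finite(reference) || reference <= 0)
    stopf("no central mosaic: reference density is zero")
  thr <- threshold_frac * reference

  border_side <- function(direction) {
    sel <- if (direction > 0) which(centres >= 0) else rev(which(centres <= 0))
    d <- dens[sel]
    below <- d < thr
    hit <- which(below[-length(below)] & below[-1])
    if (!length(hit)) return(list(border = direction * half_w,
                                  flag = "lower_bound"))
    k <- hit[1]          # innermost of the two consecutive windows
    if (k == 1) return(list(border = centres[sel[1]], flag = "ok"))
    # interpolate the threshold crossing between window k-1 (>= thr) and k
    xs <- centres[sel]
    b <- interp_crossing(xs, d, k - 1, thr)
    list(border = b, flag = "ok")
  }
  right <- border_side(+1)
  left <- border_side(-1)
  flag <- if (right$flag == "lower_bound" || left$flag == "lower_bound")
    "lower_bound" else "ok"
  structure(list(diameter = right$border - left$border,
                 borders = c(left = left$border, right = right$border),
                 flag = flag, reference_density = reference,
                 profile = profile),
            class = "impm_measurement")
}

#' @export
print.impm_measurement <- function(x, ...) {
  cat(sprintf("<impm_measurement> diameter = %.0f um [%s]\n",
              x$diameter, x$flag))
  invisible(x)
}
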