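# AOSLO phantom rendering: a jittered hexagonal cone mosaic whose local
# density follows the healthy baseline falloff scaled by the eye's foveal
# attenuation, thinned by a degeneration survival profile, and rendered as
# Gaussian spots on a confocal and a split-detection channel.

# local intact-mosaic density (cones/mm^2) before degeneration thinning
.local_density <- function(e, truth) {
  kappa <- foveal_density_truth(truth$r_ez, truth$params) /
    baseline_cone_density(100, truth$params)
  kappa * baseline_cone_density(e, truth$params)
}

# hexagonal spacing (um) at density D (cones/mm^2)
mosaic_spacing <- function(density_mm2) {
  sqrt(2 / (sqrt(3) * density_mm2 * 1e-6))
}

# survival probability of a cone at eccentricity e: ~1 inside the intact
# mosaic radius, `sparse_survival` in the annulus up to the ELM radius, and
# ~0 beyond (logistic transitions of width `transition_width`).
.survival <- function(e, truth) {
  tw <- truth$transition_width
  sp <- truth$sparse_survival
  p <- (sp + (1 - sp) * stats::plogis((truth$r_impm - e) / tw)) *
    stats::plogis((truth$r_elm - e) / tw)
  p[e > truth$r_elm + 5 * tw] <- 0
  p
}

#' Generate the ground-truth cone mosaic of one eye
#'
#' Cones are laid out on concentric rings whose radial pitch and angular
#' spacing follow the local hexagonal spacing implied by the eye's density
#' profile, with positional jitter, then thinned by the degeneration
#' survival profile.  Each cone carries a waveguiding flag; non-waveguiding
#' (dysflective) cones are omitted from the confocal rendering but present
#' on split detection.  Coordinates are micrometres relative to the fovea.
#' Only cones inside the montage strip (`config$aoslo_width_um` by
#' `config$aoslo_height_um`) are returned.  Deterministic given
#' `truth$seed`.
#'
#' @param truth a `degeneration_truth`.
#' @param config a [render_config()].
#' @return A `data.frame` of class `cone_truth_set` with columns `x`, `y`
#'   (um) and `waveguiding` (logical).
#' @export
cone_mosaic_truth <- function(truth, config = render_config()) {
  stopifnot(inherits(truth, "degeneration_truth"))
  half_w <- config$aoslo_width_um / 2
  half_h <- config$aoslo_height_um / 2
  margin <- 15  # spots just outside still shed light inside
  r_cut <- min(sqrt((half_w + margin)^2 + (half_h + margin)^2),
               truth$r_elm + 5 * truth$transition_width + margin)

  with_seed(truth$seed + 3L, {
    acc_x <- list(0); acc_y <- list(0)  # one cone at the foveal centre
    r <- mosaic_spacing(.local_density(0, truth)) * sqrt(3) / 2
    while (r <= r_cut) {
      s <- mosaic_spacing(.local_density(r, truth))
      n_k <- max(1L, round(2 * pi * r / s))
      ang <- 2 * pi * (seq_len(n_k) - 1) / n_k + stats::runif(1, 0, 2 * pi)
      px <- r * cos(ang)
      py <- r * sin(ang)
      keep <- abs(px) <= half_w + margin & abs(py) <= half_h + margin
      if (any(keep)) {
        jit <- truth$mosaic_jitter_frac * s
        acc_x[[length(acc_x) + 1L]] <-
          px[keep] + stats::rnorm(sum(keep), 0, jit)
        acc_y[[length(acc_y) + 1L]] <-
          py[keep] + stats::rnorm(sum(keep), 0, jit)
      }
      r <- r + s * sqrt(3) / 2
    }
    xs <- unlist(acc_x); ys <- unlist(acc_y)
    e <- sqrt(xs^2 + ys^2)
    keep <- stats::runif(length(e)) < .survival(e, truth)
    xs <- xs[keep]; ys <- ys[keep]
    wv <- stats::runif(length(xs)) >= truth$dysflective_fraction
    structure(data.frame(x = xs, y = ys, waveguiding = wv),
              class = c("cone_truth_set", "data.frame"))
  })
}

# Accumulate Gaussian spots (centres in px, sigma in px, per-spot) onto an
# h x w canvas.  Spots are bucketed by stamp radius so narrow spots do not
# pay for the widest one; within a bucket the loop runs over integer stamp
# offsets with vectorised scatter-adds.
.stamp_spots <- function(h, w, px, py, sigma) {
  img <- matrix(0, h, w)
  if (length(px) == 0) return(img)
  rad_all <- pmax(1L, ceiling(3 * sigma))
  for (rad in sort(unique(rad_all))) {
    sel <- rad_all == rad
    cx <- round(px[sel]); cy <- round(py[sel])
    fx <- px[sel] - cx; fy <- py[sel] - cy
    s2 <- 2 * sigma[sel]^2
    for (dx in -rad:rad) {
      col <- cx + dx
      okx <- col >= 1 & col <= w
      if (!any(okx)) next
      for (dy in -rad:rad) {
        row <- cy + dy
        ok <- okx & row >= 1 & row <= h
        if (!any(ok)) next
        val <- exp(-((dx - fx[ok])^2 + (dy - fy[ok])^2) / s2[ok])
        idx <- (col[ok] - 1L) * h + row[ok]
        agg <- rowsum(val, idx)
        ii <- as.integer(rownames(agg))
        img[ii] <- img[ii] + agg[, 1]
      }
    }
  }
  img
}

#' Render confocal and split-detection AOSLO montages
#'
#' Renders the eye's cone mosaic as Gaussian spots (width proportional to
#' the local mosaic spacing) on both detection channels: split detection
#' shows every cone (inner segments), confocal omits the non-waveguiding
#' fraction (outer-segment reflectance lost).  Additive noise is seeded
#' per channel from `truth$seed`.
#'
#' @param truth a `degeneration_truth`.
#' @param config a [render_config()].
#' @param cones optionally, a precomputed [cone_mosaic_truth()] result.
#' @return A list with elements `confocal` and `split` ([retina_image]s with
#'   the fovea at the centre) and `cones` (the `cone_truth_set`).
#' @export
render_aoslo <- function(truth, config = render_config(), cones = NULL) {
  stopifnot(inherits(truth, "degeneration_truth"))
  if (config$aoslo_width_um < 1.5 * 291 || config$aoslo_height_um < 100)
    stopf("AOSLO field must cover at least a 1.5 degree montage strip")
  if (is.null(cones)) cones <- cone_mosaic_truth(truth, config)
  sc <- config$pixel_scale_aoslo
  w <- 2L * floor(config$aoslo_width_um / 2 / sc) + 1L
  h <- 2L * floor(config$aoslo_height_um / 2 / sc) + 1L
  cx <- (w + 1L) / 2; cy <- (h + 1L) / 2

  e <- sqrt(cones$x^2 + cones$y^2)
  # spot width follows local spacing but is capped: remnant inner segments
  # enlarge somewhat in sparse retina, not without bound
  sig_um <- pmin(config$spot_sigma_frac *
                   mosaic_spacing(pmax(.local_density(e, truth), 15000)), 3)
  px <- cones$x / sc + cx
  py <- cones$y / sc + cy

  channel <- function(subset, noise_seed) {
    img <- config$aoslo_background +
      .stamp_spots(h, w, px[subset], py[subset], sig_um[subset] / sc)
    if (config$noise_sd_aoslo > 0)
      img <- img + with_seed(noise_seed,
                             matrix(stats::rnorm(h * w, 0,
                                                 config$noise_sd_aoslo), h, w))
    pmax(img, 0)
  }
  conf <- channel(cones$waveguiding, truth$seed + 4L)
  splt <- channel(rep(TRUE, nrow(cones)), truth$seed + 5L)

  list(
    confocal = retina_image(conf, pixel_scale = sc, fovea = c(cx, cy),
                            modality = "confocal", eye_id = truth$eye_id),
    split = retina_image(splt, pixel_scale = sc, fovea = c(cx, cy),
                         modality = "split_detection", eye_id = truth$eye_id),
    cones = cones
  )
}
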