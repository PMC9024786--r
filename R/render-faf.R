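# FAF phantom rendering: a radially symmetric hyperautofluorescent annulus.

#' Render a fundus autofluorescence phantom
#'
#' Radially symmetric intensity model: a low plateau inside the inner-ring
#' radius, a bright annulus between the inner and outer ring radii and an
#' intermediate level outside, with Gaussian edge profiles of width
#' `config$blur_sigma` so that the half-height crossings of the annulus sit
#' exactly at the injected radii.  Additive Gaussian noise is seeded from
#' `truth$seed`, so renders are reproducible.
#'
#' @param truth a `degeneration_truth` from [sample_cohort()].
#' @param config a [render_config()].
#' @return A [retina_image] of modality `"faf"` with the fovea at the image
#'   centre.
#' @export
render_faf <- function(truth, config = render_config()) {
  stopifnot(inherits(truth, "degeneration_truth"))
  half_um <- config$faf_size_um / 2
  if (truth$r_or + 3 * config$blur_sigma > half_um)
    stopf("outer ring (r = %.0f um) does not fit in a %.0f um field",
          truth$r_or, config$faf_size_um)
  n <- 2L * floor(half_um / config$pixel_scale_faf) + 1L
  centre <- (n + 1L) / 2
  ax <- (seq_len(n) - centre) * config$pixel_scale_faf
  r <- sqrt(outer(ax^2, ax^2, "+"))

  lv <- config$faf_levels
  s_ir <- smooth_step(r, truth$r_ir, config$blur_sigma)
  s_or <- smooth_step(r, truth$r_or, config$blur_sigma)
  img <- lv[["inner"]] * (1 - s_ir) + lv[["ring"]] * (s_ir - s_or) +
    lv[["outer"]] * s_or

  if (config$noise_sd_faf > 0)
    img <- img + with_seed(truth$seed + 1L,
                           matrix(stats::rnorm(n * n, 0, config$noise_sd_faf),
                                  n, n))
  img <- pmax(img, 0)
  retina_image(img, pixel_scale = config$pixel_scale_faf,
               fovea = c(centre, centre), modality = "faf",
               scale_flag = "linear", eye_id = truth$eye_id)
}
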