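# OCT B-scan phantom rendering: six hyperreflective depth bands with the
# photoreceptor bands laterally truncated at the degeneration radii.

#' Render a central OCT B-scan phantom
#'
#' The linear-scale image is a sum over the six layer bands (RNFL, INL, ELM,
#' EZ, IZ, RPE) of a depth Gaussian ridge times a lateral envelope.  The EZ
#' and IZ envelopes taper to zero for |lateral| > `r_ez`, the ELM envelope
#' for |lateral| > `r_elm` (Gaussian edge of width `config$oct_edge_sigma`);
#' the remaining bands span the full scan.  The stored image is the display
#' transform `I_disp = (I_lin / max)^(1/log_gamma)` and is flagged `"log"`;
#' [log_to_linear()] inverts it.
#'
#' @param truth a `degeneration_truth`.
#' @param config a [render_config()].
#' @return A [retina_image] of modality `"oct"`, `scale_flag = "log"`, fovea
#'   at the central column.
#' @export
render_oct_bscan <- function(truth, config = render_config()) {
  stopifnot(inherits(truth, "degeneration_truth"))
  half_um <- config$oct_width_um / 2
  ncols <- 2L * floor(half_um / config$pixel_scale_oct_lateral) + 1L
  nrows <- floor(config$oct_depth_um / config$pixel_scale_oct_axial)
  centre <- (ncols + 1L) / 2
  x <- (seq_len(ncols) - centre) * config$pixel_scale_oct_lateral
  z <- seq_len(nrows) * config$pixel_scale_oct_axial

  amp <- config$oct_band_amplitude
  amp["EZ"] <- truth$ez_amplitude
  amp[c("RNFL", "INL")] <- truth$inner_amplitude

  img <- matrix(config$oct_background, nrows, ncols)
  for (b in names(config$oct_band_depth_um)) {
    ridge <- amp[[b]] * exp(-(z - config$oct_band_depth_um[[b]])^2 /
                              (2 * config$oct_band_sigma_um[[b]]^2))
    env <- switch(b,
      EZ = , IZ = 1 - smooth_step(abs(x), truth$r_ez, config$oct_edge_sigma),
      ELM = 1 - smooth_step(abs(x), truth$r_elm, config$oct_edge_sigma),
      rep(1, ncols))
    img <- img + ridge %o% env
  }

  if (config$noise_sd_oct > 0)
    img <- img + with_seed(truth$seed + 2L,
                           matrix(stats::rnorm(nrows * ncols, 0,
                                               config$noise_sd_oct),
                                  nrows, ncols))
  img <- pmax(img, 0)
  disp <- (img / max(img))^(1 / config$log_gamma)
  # fovea row: depth of the EZ band, a convenient anatomical anchor
  fov_row <- config$oct_band_depth_um[["EZ"]] / config$pixel_scale_oct_axial
  retina_image(disp, pixel_scale = config$pixel_scale_oct_lateral,
               pixel_scale_axial = config$pixel_scale_oct_axial,
               fovea = c(centre, fov_row), modality = "oct",
               scale_flag = "log", eye_id = truth$eye_id)
}
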