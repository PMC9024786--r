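# helper: analytic LRP as an lr_profile object (bypasses rendering)
analytic_lrp <- function(amp_overrides = NULL, config = render_config()) {
  amps <- config$oct_band_amplitude
  if (!is.null(amp_overrides)) amps[names(amp_overrides)] <- amp_overrides
  z <- seq(config$pixel_scale_oct_axial, config$oct_depth_um,
           by = config$pixel_scale_oct_axial)
  structure(list(depth_um = z,
                 reflectance = retimetrics:::.analytic_profile(z, amps, config),
                 window_um = 1000, peaks = NULL),
            class = "lr_profile")
}

test_that("display-to-linear transform is exact and cannot double-apply", {
  z <- retina_image(matrix(0, 10, 10), 6, c(5, 5), "oct", "log",
                    pixel_scale_axial = 4)
  expect_true(all(log_to_linear(z)$grid == 0))
  g <- matrix(runif(100), 10, 10)
  s <- retina_image(g, 6, c(5, 5), "oct", "log", pixel_scale_axial = 4)
  lin1 <- log_to_linear(s, gamma = 1)
  expect_equal(lin1$grid, g / max(g))
  expect_error(log_to_linear(lin1), "already")
})

test_that("band widths recover the injected extents on a noiseless scan", {
  cfg <- render_config(noise_sd_oct = 0)
  tr <- make_truth(r_ez = 1077.5, r_elm = 1437, config = cfg)
  lin <- log_to_linear(render_oct_bscan(tr, cfg), cfg$log_gamma)
  bw <- measure_band_widths(lin, cfg$oct_band_depth_um, cfg$oct_band_sigma_um)
  expect_lt(abs(bw$ez_width - 2155), cfg$blur_sigma)
  expect_lt(abs(bw$elm_width - 2874), cfg$blur_sigma)
  expect_equal(unname(bw$flags), c("contained", "contained"))
  expect_gte(bw$elm_width, bw$ez_width)
})

test_that("a band reaching the scan edge is flagged exceeds_window", {
  cfg <- render_config(noise_sd_oct = 0)
  tr <- make_truth(r_ez = 2950, r_elm = 3100, r_ir = 2950, r_or = 3100,
                   r_impm = 3000, config = cfg)
  lin <- log_to_linear(render_oct_bscan(tr, cfg), cfg$log_gamma)
  bw <- measure_band_widths(lin, cfg$oct_band_depth_um, cfg$oct_band_sigma_um)
  expect_equal(unname(bw$flags), c("exceeds_window", "exceeds_window"))
})

test_that("a scan with no band at the fovea reports zero width", {
  cfg <- render_config()
  g <- matrix(abs(rnorm(125 * 971, 0.005, 0.002)), 125, 971)
  noisy <- retina_image(g, cfg$pixel_scale_oct_lateral, c(486, 92), "oct",
                        "linear", pixel_scale_axial = cfg$pixel_scale_oct_axial)
  w <- capture_warnings(
    bw <- measure_band_widths(noisy, cfg$oct_band_depth_um,
                              cfg$oct_band_sigma_um))
  expect_true(any(grepl("absent", w)))
  expect_equal(bw$ez_width, 0)
})

test_that("the LRP is the lateral window mean", {
  cfg <- render_config()
  g <- matrix(rep(seq(0, 1, length.out = 125), 971), 125, 971)
  s <- retina_image(g, cfg$pixel_scale_oct_lateral, c(486, 92), "oct",
                    "linear", pixel_scale_axial = cfg$pixel_scale_oct_axial)
  lrp <- longitudinal_reflectivity_profile(s)
  expect_equal(lrp$reflectance, g[, 1])  # laterally uniform = single column
  expect_error(longitudinal_reflectivity_profile(s, window_um = 99999),
               "exceeds")
  # linearity: profile mean equals the mean of the windowed image
  x <- lateral_axis_um(s)
  expect_equal(mean(lrp$reflectance), mean(g[, abs(x) <= 500]))
})

test_that("layer peaks are found, labelled in depth order, and counted", {
  cfg <- render_config(noise_sd_oct = 0)
  tr <- make_truth(config = cfg)
  lin <- log_to_linear(render_oct_bscan(tr, cfg), cfg$log_gamma)
  lrp <- identify_layer_peaks(longitudinal_reflectivity_profile(lin))
  expect_named(lrp$peaks, c("RNFL", "INL", "ELM", "EZ", "IZ", "RPE"))
  got <- lrp$depth_um[lrp$peaks]
  expect_true(all(abs(got - cfg$oct_band_depth_um) <=
                    cfg$pixel_scale_oct_axial))
  expect_true(all(diff(lrp$peaks) > 0))
  # removing the EZ band leaves five peaks and a counting error
  expect_error(identify_layer_peaks(analytic_lrp(c(EZ = 0))), "5")
})

test_that("tied prominences keep the deeper peak", {
  # seven candidate peaks: six tall plus two identical small ones; only one
  # of the two small twins can be labelled and it must be the deeper one
  y <- rep(0.01, 200)
  tall <- c(20, 50, 80, 110, 140)
  for (p in tall) y[p + (-3:3)] <- c(.2, .5, .9, 1, .9, .5, .2)
  for (p in c(170, 185)) y[p + (-2:2)] <- c(.1, .3, .4, .3, .1)
  lrp <- structure(list(depth_um = seq_len(200), reflectance = y,
                        window_um = 1000, peaks = NULL),
                   class = "lr_profile")
  out <- identify_layer_peaks(lrp)
  expect_true(185 %in% out$peaks)
  expect_false(170 %in% out$peaks)
})

test_that("normalised EZ reflectance matches the analytic phantom ratio", {
  cfg <- render_config()
  for (target in c(3, 5.79, 9)) {
    tr <- make_truth(norm_reflectance = target, config = cfg)
    lin <- log_to_linear(render_oct_bscan(tr, cfg), cfg$log_gamma)
    r <- normalized_ez_reflectance(
      identify_layer_peaks(longitudinal_reflectivity_profile(lin)))
    expect_lt(abs(r / target - 1), 0.05)
  }
})

test_that("the reflectance ratio is scale invariant and 1 on a flat profile", {
  cfg <- render_config()
  tr <- make_truth(config = cfg)
  lin <- log_to_linear(render_oct_bscan(tr, cfg), cfg$log_gamma)
  lrp <- identify_layer_peaks(longitudinal_reflectivity_profile(lin))
  r1 <- normalized_ez_reflectance(lrp)
  lrp10 <- lrp
  lrp10$reflectance <- 10 * lrp$reflectance
  lrp10$prominence <- 10 * lrp$prominence
  expect_equal(normalized_ez_reflectance(lrp10), r1, tolerance = 1e-12)
  flat <- structure(list(depth_um = seq_len(125) * 4,
                         reflectance = rep(0.4, 125), window_um = 1000,
                         peaks = c(RNFL = 25, INL = 50, ELM = 84, EZ = 92,
                                   IZ = 101, RPE = 111),
                         prominence = c(RNFL = 0, INL = 0, ELM = 0, EZ = 0,
                                        IZ = 0, RPE = 0)),
                    class = "lr_profile")
  expect_equal(normalized_ez_reflectance(flat), 1.0)
})

test_that("ELM width is at least EZ width across noiseless phantoms", {
  cfg <- render_config(noise_sd_oct = 0)
  for (r in c(400, 900, 1600)) {
    tr <- make_truth(r_ez = r, r_elm = r + 300, r_ir = r, r_or = r + 300,
                     r_impm = r + 150, config = cfg)
    lin <- log_to_linear(render_oct_bscan(tr, cfg), cfg$log_gamma)
    bw <- measure_band_widths(lin, cfg$oct_band_depth_um,
                              cfg$oct_band_sigma_um)
    expect_gte(bw$elm_width, bw$ez_width)
  }
})
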