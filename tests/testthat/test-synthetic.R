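test_that("cohort sampling is reproducible and respects the geometry", {
  a <- sample_cohort(16, seed = 3)
  b <- sample_cohort(16, seed = 3)
  expect_identical(a, b)
  expect_equal(length(a$eyes), 32)
  for (tr in a$eyes) {
    expect_lte(tr$r_ez, tr$r_elm)
    expect_lte(tr$r_ir, tr$r_or)
    expect_true(tr$r_impm >= tr$r_ez && tr$r_impm <= tr$r_elm)
    expect_true(all(c(tr$r_ez, tr$r_ir, tr$r_or, tr$r_impm) >= 0))
    expect_true(tr$dysflective_fraction >= 0 && tr$dysflective_fraction <= 1)
  }
  expect_false(identical(a, sample_cohort(16, seed = 4)))
})

test_that("injected cross-modality offsets are recovered in the mean", {
  coh <- sample_cohort(250, seed = 5)
  tab <- do.call(rbind, lapply(coh$eyes, truth_biomarkers))
  d_ir <- tab$ir_diameter_um - tab$ez_width_um
  d_or <- tab$or_diameter_um - tab$elm_width_um
  d_impm <- tab$impm_diameter_um - tab$ez_width_um
  # 500 eyes: standard error ~ sd/sqrt(500) ~ 3
  expect_lt(abs(mean(d_ir) - (-8)), 3 * 66 / sqrt(500) * 3)
  expect_lt(abs(mean(d_or) - (-39)), 3 * 76 / sqrt(500) * 3)
  expect_gt(mean(d_impm), 0)  # mosaic border lateral to EZ loss
})

test_that("biphasic density truth is continuous, clipped and plateaus", {
  p <- truth_params()
  c0 <- p$density_breakpoint
  eps <- 1e-9
  expect_equal(foveal_density_truth(c0 - eps, p),
               foveal_density_truth(c0 + eps, p), tolerance = 1e-6)
  expect_equal(foveal_density_truth(c0, p), 0.5 * p$baseline_density_100)
  expect_gte(foveal_density_truth(0, p), 0)
  # steep below, shallow above
  below <- foveal_density_truth(c0 - 100, p) - foveal_density_truth(c0 - 200, p)
  above <- foveal_density_truth(c0 + 200, p) - foveal_density_truth(c0 + 100, p)
  expect_gt(below, above)
  # large intact EZ: near the degeneration-free plateau (half of healthy)
  expect_lt(abs(foveal_density_truth(3500, p) / (0.5 * p$baseline_density_100) - 1),
            0.15)
  expect_error(foveal_density_truth(-5, p), "non-negative")
})

test_that("truth biomarkers double the radii and hit the reflectance target", {
  cfg <- render_config()
  tr <- make_truth(r_ez = 1077.5, r_elm = 1437, norm_reflectance = 5.79,
                   config = cfg)
  tb <- truth_biomarkers(tr, cfg)
  expect_equal(tb$ez_width_um, 2155)
  expect_equal(tb$elm_width_um, 2874)
  expect_equal(tb$ir_diameter_um, 2 * tr$r_ir)
  # EZ fully inside the LRP window: analytic ratio equals the target
  expect_equal(tb$norm_ez_reflectance, 5.79, tolerance = 1e-8)
  expect_equal(tb$cone_density_mm2, foveal_density_truth(1077.5, tr$params))
})

test_that("FAF rendering places half-height edges at the injected radii", {
  cfg <- render_config(noise_sd_faf = 0)
  tr <- make_truth(r_ir = 1176, r_or = 1736, config = cfg)
  img <- render_faf(tr, cfg)
  prof <- horizontal_profile(img)
  lv <- cfg$faf_levels
  # interpolated crossing of the inner half level on the right side
  x <- prof$x_um; y <- prof$intensity
  half_in <- (lv[["inner"]] + lv[["ring"]]) / 2
  i <- max(which(x < 1176 & x > 0 & y <= half_in))
  edge <- x[i] + (half_in - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
  expect_lt(abs(edge - 1176), cfg$blur_sigma)
  # blur -> 0 gives a piecewise-constant annulus
  cfg0 <- render_config(noise_sd_faf = 0, blur_sigma = 0)
  img0 <- render_faf(make_truth(config = cfg0), cfg0)
  expect_setequal(unique(as.vector(img0$grid)), unname(cfg0$faf_levels))
  # ring larger than the field is refused
  expect_error(render_faf(make_truth(r_or = 5000, r_elm = 5100,
                                     r_impm = 4000, config = cfg), cfg),
               "does not fit")
  # two seeds differ only in noise
  cfgn <- render_config(noise_sd_faf = 0.03)
  t1 <- make_truth(seed = 1, config = cfgn)
  t2 <- make_truth(seed = 2, config = cfgn)
  d <- render_faf(t1, cfgn)$grid - render_faf(t2, cfgn)$grid
  expect_lt(abs(mean(d)), 1e-3)
  expect_equal(sd(d), sqrt(2) * 0.03, tolerance = 0.05)
})

test_that("OCT rendering has six ordered bands with correct truncation", {
  cfg <- render_config(noise_sd_oct = 0)
  tr <- make_truth(config = cfg)
  scan <- render_oct_bscan(tr, cfg)
  lin <- log_to_linear(scan, cfg$log_gamma)
  x <- lateral_axis_um(lin); z <- axial_axis_um(lin)
  centre_col <- lin$grid[, which.min(abs(x))]
  pk <- which(diff(sign(diff(centre_col))) == -2) + 1
  expect_equal(length(pk), 6)
  expect_true(all(abs(z[pk] - cfg$oct_band_depth_um) <= 4))
  # between r_ez and r_elm the ELM survives but the EZ is gone
  mid_col <- lin$grid[, which.min(abs(x - (tr$r_ez + tr$r_elm) / 2))]
  z_ez <- abs(z - cfg$oct_band_depth_um[["EZ"]]) <= 10
  z_elm <- abs(z - cfg$oct_band_depth_um[["ELM"]]) <= 10
  expect_gt(max(mid_col[z_elm]), 10 * max(mid_col[z_ez]))
  # display round-trip recovers the linear image up to scale
  relin <- log_to_linear(scan, cfg$log_gamma)
  disp2 <- (relin$grid / max(relin$grid))^(1 / cfg$log_gamma)
  expect_lt(max(abs(disp2 - scan$grid / max(scan$grid))), 1e-6)
})

test_that("cone mosaic matches its density law and separation invariant", {
  cfg <- fast_config()
  tr <- make_truth(config = cfg)
  cones <- cone_mosaic_truth(tr, cfg)
  expect_identical(cones, cone_mosaic_truth(tr, cfg))  # deterministic
  # window count at 100 um within 3 Poisson sd of the density law
  cnt <- sum(abs(cones$x - 100) <= 50 & abs(cones$y) <= 50)
  expected <- foveal_density_truth(tr$r_ez, tr$params) * 0.01
  expect_lt(abs(cnt - expected), 3 * sqrt(expected))
  # no cones beyond the ELM radius (outer-ring equivalent)
  e <- sqrt(cones$x^2 + cones$y^2)
  expect_equal(sum(e > tr$r_elm + 5 * tr$transition_width), 0)
  # pairwise separation above half the local lattice spacing (sampled)
  inner <- cones[e < 500, ]
  d <- as.matrix(stats::dist(inner[, c("x", "y")])); diag(d) <- Inf
  s_local <- sqrt(2 / (sqrt(3) * foveal_density_truth(tr$r_ez, tr$params) * 1e-6))
  expect_gt(min(d), 0.5 * s_local)
})

test_that("dysflective cones are hidden from confocal but not split detection", {
  cfg <- fast_config()
  tr <- make_truth(config = cfg, dysflective_fraction = 0.25)
  ao <- render_aoslo(tr, cfg)
  expect_equal(nrow(ao$cones),
               sum(ao$cones$waveguiding) / (1 - 0.25), tolerance = 0.1)
  cfg0 <- fast_config(noise_sd_aoslo = 0)
  tr0 <- make_truth(config = cfg0, dysflective_fraction = 0)
  ao0 <- render_aoslo(tr0, cfg0)
  expect_true(all(ao0$cones$waveguiding))
  expect_identical(ao0$confocal$grid, ao0$split$grid)
})

test_that("truth JSON round-trips", {
  tr <- make_truth()
  f <- tempfile(fileext = ".json")
  write_truth_json(tr, f)
  tr2 <- read_truth_json(f)
  expect_equal(tr2$r_ez, tr$r_ez)
  expect_equal(tr2$seed, tr$seed)
  expect_identical(cone_mosaic_truth(tr2, fast_config()),
                   cone_mosaic_truth(tr, fast_config()))
})
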