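test_that("retinal magnification scales linearly with axial length", {
  expect_equal(micrometres_per_degree(24.00), 291)
  expect_equal(micrometres_per_degree(23.88), 289.545)
  expect_equal(round(micrometres_per_degree(27.09), 2), 328.47)
  al <- seq(20, 30, by = 0.5)
  expect_true(all(diff(micrometres_per_degree(al)) > 0))
  expect_error(micrometres_per_degree(19.9), "range")
})

test_that("sampling windows sit at +/- eccentricity on the meridian", {
  img <- retina_image(matrix(0.5, 301, 601), 1, c(301, 151), "split_detection")
  w <- place_sampling_windows(img)
  expect_equal(vapply(w, function(x) x$centre_um[["x"]], numeric(1)),
               c(-100, 100))
  expect_equal(w[[1]]$size_um^2 / 1e6, 0.01)  # 0.01 mm^2
  expect_warning(place_sampling_windows(img, eccentricity_um = 0), "overlap")
  small <- retina_image(matrix(0.5, 80, 80), 1, c(40, 40), "split_detection")
  expect_error(place_sampling_windows(small), "outside")
})

test_that("cone detection is exact on a noiseless regular lattice", {
  # hexagonal lattice, spacing 8 um, rendered as clean Gaussian spots
  s <- 8
  rows <- seq(-70, 70, by = s * sqrt(3) / 2)
  pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
    xo <- if (i %% 2 == 0) s / 2 else 0
    x <- seq(-70, 70, by = s) + xo + 0.7
    cbind(x, rows[i] + 0.7)
  }))
  h <- w <- 161
  grid <- retimetrics:::.stamp_spots(h, w, pts[, 1] + 81, pts[, 2] + 81,
                                     rep(1.6, nrow(pts)))
  img <- retina_image(grid, 1, c(81, 81), "split_detection")
  cones <- detect_cones(img, expected_spacing_um = 8)
  win <- abs(cones$x_um) <= 50 & abs(cones$y_um) <= 50
  truth_in <- abs(pts[, 1]) <= 50 & abs(pts[, 2]) <= 50
  expect_equal(sum(win), sum(truth_in))
  # blank window yields an empty set
  blank <- retina_image(matrix(0.1, 121, 121), 1, c(61, 61),
                        "split_detection")
  expect_equal(nrow(detect_cones(blank, 8)), 0)
})

test_that("detection count is invariant to global intensity scaling", {
  cfg <- fast_config()
  ao <- render_aoslo(make_truth(config = cfg), cfg)
  w <- place_sampling_windows(ao$split)[[2]]
  c1 <- detect_cones(extract_window(ao$split, w), 4.5)
  bright <- ao$split
  bright$grid <- bright$grid * 10
  c2 <- detect_cones(extract_window(bright, w), 4.5)
  expect_equal(nrow(c1), nrow(c2))
})

test_that("modality choice prefers more cones, split detection on ties", {
  mk <- function(n, modality) {
    structure(data.frame(x_um = seq_len(n), y_um = seq_len(n)),
              class = c("cone_set", "data.frame"), modality = modality,
              window = list(size_um = 100))
  }
  expect_equal(attr(choose_modality(mk(80, "confocal"),
                                    mk(100, "split_detection")), "modality"),
               "split_detection")
  expect_equal(attr(choose_modality(mk(100, "confocal"),
                                    mk(100, "split_detection")), "modality"),
               "split_detection")
  expect_equal(attr(choose_modality(mk(101, "confocal"),
                                    mk(100, "split_detection")), "modality"),
               "confocal")
})

test_that("split detection wins on dysflective mosaics", {
  cfg <- fast_config()
  chosen <- character(0)
  for (seed in 1:4) {
    tr <- make_truth(seed = seed, config = cfg, dysflective_fraction = 0.3)
    ao <- render_aoslo(tr, cfg)
    d <- foveal_cone_density(ao$confocal, ao$split)
    chosen <- c(chosen, d$windows$modality)
  }
  expect_gte(mean(chosen == "split_detection"), 0.95)
})

test_that("cone density is count over window area", {
  cones <- structure(data.frame(x_um = runif(562), y_um = runif(562)),
                     class = c("cone_set", "data.frame"))
  expect_equal(cone_density(cones, window_size_um = 100), 56200)
  empty <- structure(data.frame(x_um = numeric(0), y_um = numeric(0)),
                     class = c("cone_set", "data.frame"))
  expect_equal(cone_density(empty, window_size_um = 100), 0)
})

test_that("detected foveal density tracks the truth coordinates", {
  cfg <- fast_config()
  rel <- vapply(1:3, function(seed) {
    tr <- make_truth(seed = seed, config = cfg)
    ao <- render_aoslo(tr, cfg)
    d <- foveal_cone_density(ao$confocal, ao$split)
    cnt <- (sum(abs(ao$cones$x - 100) <= 50 & abs(ao$cones$y) <= 50) +
            sum(abs(ao$cones$x + 100) <= 50 & abs(ao$cones$y) <= 50)) / 2 / 0.01
    d$density / cnt - 1
  }, numeric(1))
  expect_lt(stats::median(abs(rel)), 0.05)
})

test_that("intact-mosaic diameter is recovered on sharp-edged phantoms", {
  cfg <- render_config(aoslo_width_um = 4000, aoslo_height_um = 260)
  tr <- make_truth(r_impm = 1377, config = cfg, sparse_survival = 0)
  ao <- render_aoslo(tr, cfg)
  m <- measure_impm_diameter(ao$split)
  expect_equal(m$flag, "ok")
  expect_lt(abs(m$diameter - 2754), 100)
})

test_that("fully intact and fully empty mosaics are flagged or refused", {
  cfg <- fast_config()
  # intact beyond the montage: no dropout before the edge
  tr <- make_truth(r_ez = 1800, r_elm = 2400, r_ir = 1800, r_or = 2400,
                   r_impm = 2100, config = cfg)
  ao <- render_aoslo(tr, cfg)
  m <- measure_impm_diameter(ao$split)
  expect_equal(m$flag, "lower_bound")
  # no central mosaic at all: no reference density
  blank <- retina_image(matrix(0, 261, 2001), 1, c(1001, 131),
                        "split_detection")
  expect_error(measure_impm_diameter(blank), "no central mosaic")
})
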