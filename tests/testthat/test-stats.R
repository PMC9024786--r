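test_that("pearson_r2 matches direct formulas and handles edge cases", {
  x <- c(1, 2, 3, 4, 5)
  r <- pearson_r2(x, 2 * x)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)

  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(20); y <- 0.5 * x + rnorm(20)
    got <- pearson_r2(x, y)
    # independent covariance-formula oracle
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    r_o <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t_o <- r_o * sqrt(18 / (1 - r_o^2))
    expect_equal(got$r, r_o, tolerance = 1e-12)
    expect_equal(got$p_value, 2 * pt(-abs(t_o), 18), tolerance = 1e-12)
    expect_equal(got$slope, sxy / sum((x - mean(x))^2), tolerance = 1e-12)
    # r and r^2 are symmetric in (x, y)
    swapped <- pearson_r2(y, x)
    expect_equal(swapped$r_squared, got$r_squared)
  }

  set.seed(10)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(pearson_r2(x, y)$r_squared, 0.01)
  expect_error(pearson_r2(1:2, 1:2), "3")
  expect_error(pearson_r2(rep(1, 5), 1:5), "zero variance")
})

test_that("mean_difference reports paired agreement statistics", {
  a <- c(1, 2, 3)
  expect_equal(mean_difference(a, a)$mean_difference, 0)
  expect_equal(mean_difference(a, a)$sd_difference, 0)
  d <- mean_difference(a, a + 5)
  expect_equal(d$mean_difference, -5)
  expect_equal(d$sd_difference, 0)
  expect_error(mean_difference(1:3, 1:4), "equal length")
  expect_error(mean_difference(1, 1), "2")
})

test_that("hinge fit recovers a noiseless breakpoint exactly on the grid", {
  x <- seq(500, 5000, by = 50)
  y <- 56000 + 14 * pmin(x - 2700, 0) + 1 * pmax(x - 2700, 0)
  f <- fit_biphasic(x, y, grid_step = 25)
  expect_equal(f$breakpoint, 2700)
  expect_equal(f$slope_below, 14, tolerance = 1e-8)
  expect_equal(f$slope_above, 1, tolerance = 1e-8)
  expect_equal(f$sse_piecewise, 0, tolerance = 1e-12)
  expect_false(f$unstable)
})

test_that("hinge SSE never exceeds the single-line SSE", {
  set.seed(11)
  for (i in 1:10) {
    x <- runif(40, 0, 6000)
    y <- rnorm(40, 50000, 5000)
    f <- fit_biphasic(x, y)
    expect_lte(f$sse_piecewise, f$sse_linear + 1e-9)
  }
})

test_that("purely linear data flags an unstable breakpoint", {
  set.seed(12)
  x <- runif(50, 0, 5000)
  y <- 10000 + 3 * x
  f <- fit_biphasic(x, y)
  expect_true(f$unstable)
  expect_equal(f$sse_piecewise, f$sse_linear, tolerance = 1e-6)
  # with noise the hinge gains little over the line
  yn <- y + rnorm(50, 0, 200)
  fn <- fit_biphasic(x, yn)
  expect_lt((fn$sse_linear - fn$sse_piecewise) / fn$sse_linear, 0.15)
  expect_error(fit_biphasic(1:5, 1:5), "6")
})

test_that("biphasic fit methods are mutually consistent", {
  set.seed(13)
  x <- runif(60, 0, 5400)
  y <- 56000 + 25 * pmin(x - 2700, 0) + rnorm(60, 0, 1500)
  f <- fit_biphasic(x, y)
  expect_named(coef(f), c("breakpoint", "intercept", "slope_below",
                          "slope_above"))
  expect_equal(residuals(f), f$y - predict(f))
  expect_equal(predict(f, f$breakpoint), f$intercept)
  expect_lt(abs(f$breakpoint - 2700), 300)
  # brute-force least squares at the chosen breakpoint agrees
  X <- cbind(1, pmin(x - f$breakpoint, 0), pmax(x - f$breakpoint, 0))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sse <- sum((y - X %*% beta)^2)
  expect_equal(f$sse_piecewise, sse, tolerance = 1e-10)
})

test_that("biomarker report wires averaging, agreement and exclusions", {
  set.seed(14)
  n <- 8
  ids <- sprintf("P%02d", seq_len(n))
  ez <- runif(2 * n, 800, 5200)
  bio <- data.frame(
    subject_id = rep(ids, each = 2),
    ir_diameter_um = ez - 8 + rnorm(2 * n, 0, 66),
    or_diameter_um = ez + 680 + rnorm(2 * n, 0, 76),
    ez_width_um = ez,
    elm_width_um = ez + 719,
    norm_ez_reflectance = runif(2 * n, 3, 9),
    cone_density_mm2 = 56000 + 25 * pmin(ez - 2700, 0),
    impm_diameter_um = ez + 292)
  cohort <- data.frame(subject_id = ids, age = 20 + seq_len(n) * 4,
                       bcva_od = 0.8, bcva_os = 0.6)
  rep1 <- biomarker_report(bio, cohort)
  ir_ez <- rep1$cross_modality[1, ]
  expect_equal(ir_ez$n, n)
  expect_gt(ir_ez$r_squared, 0.95)
  expect_true(abs(ir_ez$mean_difference + 8) < 66)
  expect_equal(rep1$subject_metrics$bcva, rep(0.7, n))

  # one missing eye still leaves the subject in (other eye passes through);
  # both eyes missing excludes the subject pairwise
  bio2 <- bio
  bio2$ez_width_um[1] <- NA
  expect_equal(biomarker_report(bio2, cohort)$cross_modality[1, "n"], n)
  bio2$ez_width_um[2] <- NA
  expect_equal(biomarker_report(bio2, cohort)$cross_modality[1, "n"], n - 1)

  # a cohort of one cannot support correlations and says so
  r1 <- biomarker_report(bio[1:2, ], cohort[1, ])
  expect_true(all(is.na(r1$cross_modality$r_squared)))
  expect_true(any(grepl("3", r1$cross_modality$note)))

  # per-eye sensitivity mode uses every eye as a row
  r_eye <- biomarker_report(bio, cohort, per_eye = TRUE)
  expect_equal(r_eye$cross_modality$n[1], 2 * n)
  expect_equal(nrow(r_eye$subject_metrics), 2 * n)
})
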