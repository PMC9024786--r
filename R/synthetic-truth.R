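# Ground-truth generation for the synthetic retinal cohort.
#
# One "truth" object per eye carries the degeneration geometry (radial
# extents of the intact EZ/ELM bands, the FAF ring radii, the intact-mosaic
# radius), the cone-density model parameters and the rendering seed.  All
# extents are radial micrometres from the fovea; reported biomarkers are the
# corresponding horizontal diameters (twice the radius).

#' Rendering configuration for the synthetic modalities
#'
#' Pixel scales, field sizes, edge blur, noise levels and the OCT band model
#' (depth positions, axial widths and peak amplitudes of the six
#' hyperreflective layers RNFL, INL, ELM, EZ, IZ, RPE).  Defaults emulate a
#' 30 degree fundus autofluorescence frame, a 20 degree OCT B-scan and a
#' wide-field AOSLO montage strip at 1 um/px.
#'
#' @param pixel_scale_faf,pixel_scale_oct_lateral,pixel_scale_oct_axial,pixel_scale_aoslo
#'   pixel scales in micrometres per pixel.
#' @param faf_size_um FAF field width/height (um); 30 deg at 291 um/deg.
#' @param oct_width_um,oct_depth_um OCT B-scan lateral width and depth (um).
#' @param aoslo_width_um,aoslo_height_um AOSLO montage strip extent (um).
#' @param blur_sigma FAF edge blur (um, Gaussian edge profile).
#' @param oct_edge_sigma lateral taper width of OCT band truncation (um).
#' @param noise_sd_faf,noise_sd_oct,noise_sd_aoslo additive Gaussian noise
#'   standard deviations (linear intensity units).
#' @param log_gamma exponent of the power-law display transform applied to
#'   the linear OCT image (display = linear^(1/log_gamma)); must be >= 1.
#' @param faf_levels intensity plateau levels inside the inner ring, on the
#'   hyperautofluorescent annulus, and outside the outer ring.
#' @param oct_band_depth_um,oct_band_sigma_um,oct_band_amplitude named
#'   vectors (RNFL, INL, ELM, EZ, IZ, RPE) of band centre depths, axial
#'   Gaussian widths and linear peak amplitudes; the EZ amplitude is
#'   calibrated per eye from its normalised-reflectance target and the value
#'   given here is only a placeholder.
#' @param oct_background constant linear background reflectance.
#' @param spot_sigma_frac AOSLO cone spot width as a fraction of the local
#'   mosaic spacing.
#' @param aoslo_background constant AOSLO background level.
#' @return A list of class `render_config`.
#' @export
render_config <- function(pixel_scale_faf = 10,
                          pixel_scale_oct_lateral = 6,
                          pixel_scale_oct_axial = 4,
                          pixel_scale_aoslo = 1,
                          faf_size_um = 8730,
                          oct_width_um = 5820,
                          oct_depth_um = 500,
                          aoslo_width_um = 7000,
                          aoslo_height_um = 300,
                          blur_sigma = 25,
                          oct_edge_sigma = 3,
                          noise_sd_faf = 0.03,
                          noise_sd_oct = 0.002,
                          noise_sd_aoslo = 0.05,
                          log_gamma = 4,
                          faf_levels = c(inner = 0.25, ring = 1.0,
                                         outer = 0.55),
                          oct_band_depth_um = c(RNFL = 100, INL = 200,
                                                ELM = 335, EZ = 370,
                                                IZ = 405, RPE = 445),
                          oct_band_sigma_um = c(RNFL = 8, INL = 9, ELM = 5,
                                                EZ = 7, IZ = 5, RPE = 10),
                          oct_band_amplitude = c(RNFL = 0.10, INL = 0.10,
                                                 ELM = 0.12, EZ = 0.18,
                                                 IZ = 0.08, RPE = 0.18),
                          oct_background = 0.005,
                          spot_sigma_frac = 0.20,
                          aoslo_background = 0.10) {
  cfg <- as.list(environment())
  scales <- c(cfg$pixel_scale_faf, cfg$pixel_scale_oct_lateral,
              cfg$pixel_scale_oct_axial, cfg$pixel_scale_aoslo)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stopf("all pixel scales must be positive")
  if (cfg$log_gamma < 1) stopf("log_gamma must be >= 1")
  band_names <- c("RNFL", "INL", "ELM", "EZ", "IZ", "RPE")
  if (!identical(names(cfg$oct_band_depth_um), band_names))
    stopf("oct_band_depth_um must be named %s", paste(band_names, collapse = ", "))
  if (is.unsorted(cfg$oct_band_depth_um, strictly = TRUE))
    stopf("OCT band depths must be strictly increasing")
  structure(cfg, class = "render_config")
}

#' Cohort-level parameters of the synthetic degeneration model
#'
#' Distributional defaults reproduce the dispersion of the clinical cohort
#' the generator emulates: EZ width lognormal with mean 2155 and SD 1254 um;
#' inner-ring diameter offset from EZ width of -8 um (SD 66); outer-ring
#' offset from ELM width of -39 um (SD 76); intact-mosaic diameter offset
#' from EZ width of +292 um (SD 201); ELM width offset from EZ width of
#' +719 um (SD 300, truncated at 0); normalised EZ reflectance 5.79
#' (SD 2.64, truncated at 1).
#'
#' The cone-density model has two parts.  A healthy baseline falloff
#' `D_base(e) = D_peak * (1 + e/e_half)^(-beta)` with `D_base(100) =
#' baseline_density_100`; and a biphasic dependence of the density at 100 um
#' eccentricity on the intact-EZ radius `r_ez`: a hinge at
#' `density_breakpoint` um with a shallow slope above and a steep slope
#' below, continuous at the hinge where it equals half the healthy baseline.
#'
#' @param ez_width_mean,ez_width_sd lognormal moments of EZ width (um).
#' @param eye_asym_log_sd within-subject log-scale eye asymmetry of EZ width.
#' @param ir_offset,ir_offset_sd,or_offset,or_offset_sd,impm_offset,impm_offset_sd,elm_offset,elm_offset_sd
#'   diameter offsets and jitters (um), as described above.
#' @param density_breakpoint hinge position (radial um; default 1350).
#' @param density_slow_slope,density_fast_slope cone-density slopes above and
#'   below the hinge (cones/mm^2 per radial um).
#' @param baseline_density_100 healthy cone density at 100 um eccentricity
#'   (cones/mm^2).
#' @param baseline_e_half,baseline_beta baseline falloff shape parameters.
#' @param dysflective_fraction proportion of cones rendered invisible on the
#'   confocal channel (non-waveguiding) while present on split detection.
#' @param sparse_survival cone survival fraction in the annulus between the
#'   intact-mosaic radius and the ELM radius.
#' @param transition_width logistic width of the survival transitions (um).
#' @param mosaic_jitter_frac positional jitter of mosaic cones as a fraction
#'   of local spacing.
#' @param norm_reflectance_mean,norm_reflectance_sd per-eye normalised EZ
#'   reflectance target distribution.
#' @param inner_amplitude linear peak amplitude of the inner retinal bands.
#' @param axial_length_mean,axial_length_sd axial length distribution (mm),
#'   clipped to \[21, 27\].
#' @param age_range subject age range (uniform integer draw).
#' @return A list of class `truth_params`.
#' @export
truth_params <- function(ez_width_mean = 2155,
                         ez_width_sd = 1254,
                         eye_asym_log_sd = 0.03,
                         ir_offset = -8, ir_offset_sd = 66,
                         or_offset = -39, or_offset_sd = 76,
                         impm_offset = 292, impm_offset_sd = 201,
                         elm_offset = 719, elm_offset_sd = 300,
                         density_breakpoint = 1350,
                         density_slow_slope = 2,
                         density_fast_slope = 28,
                         baseline_density_100 = 112000,
                         baseline_e_half = 800,
                         baseline_beta = 1,
                         dysflective_fraction = 0.25,
                         sparse_survival = 0.2,
                         transition_width = 20,
                         mosaic_jitter_frac = 0.05,
                         norm_reflectance_mean = 5.79,
                         norm_reflectance_sd = 2.64,
                         inner_amplitude = 0.10,
                         axial_length_mean = 23.7,
                         axial_length_sd = 1.2,
                         age_range = c(19, 55)) {
  p <- as.list(environment())
  if (p$ez_width_mean <= 0 || p$ez_width_sd <= 0)
    stopf("EZ width distribution moments must be positive")
  if (p$dysflective_fraction < 0 || p$dysflective_fraction > 1)
    stopf("dysflective_fraction must lie in [0, 1]")
  if (p$sparse_survival < 0 || p$sparse_survival > 1)
    stopf("sparse_survival must lie in [0, 1]")
  structure(p, class = "truth_params")
}

# Lognormal parameters matching a target mean/sd on the natural scale.
.lognorm_pars <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Healthy baseline cone-density falloff
#'
#' @param eccentricity_um radial eccentricity (um), vectorised.
#' @param params a [truth_params()] list.
#' @return baseline density (cones/mm^2).
#' @export
baseline_cone_density <- function(eccentricity_um, params = truth_params()) {
  peak <- params$baseline_density_100 *
    (1 + 100 / params$baseline_e_half)^params$baseline_beta
  peak * (1 + eccentricity_um / params$baseline_e_half)^(-params$baseline_beta)
}

#' Biphasic ground-truth foveal cone density
#'
#' Continuous piecewise-linear ("hinge") dependence of the cone density at
#' 100 um eccentricity on the radial extent of the intact EZ band: at the
#' hinge (`density_breakpoint`, default 1350 um) the density equals half the
#' healthy baseline at 100 um; above the hinge it rises with the shallow
#' slope (near-plateau), below it falls with the steep slope; clipped at 0.
#'
#' @param r_ez radial extent of the intact EZ band (um), vectorised.
#' @param params a [truth_params()] list.
#' @return cone density at 100 um eccentricity (cones/mm^2).
#' @export
foveal_density_truth <- function(r_ez, params = truth_params()) {
  if (any(r_ez < 0)) stopf("r_ez must be non-negative")
  hinge_density <- 0.5 * params$baseline_density_100
  d <- r_ez - params$density_breakpoint
  dens <- hinge_density +
    ifelse(d >= 0, params$density_slow_slope * d, params$density_fast_slope * d)
  pmax(dens, 0)
}

#' Sample a synthetic cohort of per-eye degeneration truths
#'
#' Draws `n_subjects` subjects with two eyes each.  The subject-level EZ
#' width is lognormal; eyes deviate from it by a small lognormal asymmetry.
#' Ring, ELM and intact-mosaic extents follow the EZ width with the offsets
#' and jitters in `params`; draws violating the geometric invariants
#' (`r_ez <= r_elm`, `r_ir <= r_or`, `r_ez <= r_impm <= r_elm`, all radii
#' >= 0) are resampled.  Age is uniform over `age_range` and a plausible
#' acuity is attached, declining with EZ width.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @param config a [render_config()]; used to calibrate the rendered EZ band
#'   amplitude from the eye's normalised-reflectance target.
#' @param params a [truth_params()].
#' @return A list of class `synthetic_cohort` with elements `eyes` (list of
#'   `degeneration_truth` objects, two per subject) and `subjects` (a
#'   `cohort_table`-shaped data frame with synthetic demographics).
#' @export
sample_cohort <- function(n_subjects, seed = 1L,
                          config = render_config(),
                          params = truth_params()) {
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  stopifnot(inherits(config, "render_config"), inherits(params, "truth_params"))
  ln <- .lognorm_pars(params$ez_width_mean, params$ez_width_sd)

  with_seed(seed, {
    subj_ez <- stats::rlnorm(n_subjects, ln["meanlog"], ln["sdlog"])
    ages <- sample(seq(params$age_range[1], params$age_range[2]),
                   n_subjects, replace = TRUE)
    eyes <- vector("list", 2L * n_subjects)
    subj_rows <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      sid <- sprintf("P%02d", i)
      al <- pmin(pmax(stats::rnorm(2, params$axial_length_mean,
                                   params$axial_length_sd), 21), 27)
      bcva <- numeric(2)
      for (e in 1:2) {
        eye <- c("OD", "OS")[e]
        repeat {
          ez_d <- subj_ez[i] * exp(stats::rnorm(1, 0, params$eye_asym_log_sd))
          elm_d <- ez_d + stats::rnorm(1, params$elm_offset,
                                       params$elm_offset_sd)
          ir_d <- ez_d + stats::rnorm(1, params$ir_offset, params$ir_offset_sd)
          or_d <- elm_d + stats::rnorm(1, params$or_offset,
                                       params$or_offset_sd)
          impm_d <- ez_d + stats::rnorm(1, params$impm_offset,
                                        params$impm_offset_sd)
          ok <- elm_d >= ez_d && ir_d >= 0 && or_d >= ir_d &&
            impm_d >= ez_d && impm_d <= elm_d && ez_d > 0
          if (ok) break
        }
        target <- -1
        while (target < 1)
          target <- stats::rnorm(1, params$norm_reflectance_mean,
                                 params$norm_reflectance_sd)
        # acuity declines with EZ width, with residual scatter
        bcva[e] <- min(1.25, max(0.1,
          0.77 * sqrt(ez_d / params$ez_width_mean) + stats::rnorm(1, 0, 0.12)))
        truth <- structure(list(
          eye_id = paste0(sid, "_", eye),
          subject_id = sid, eye = eye,
          r_ez = ez_d / 2, r_elm = elm_d / 2,
          r_ir = ir_d / 2, r_or = or_d / 2,
          r_impm = impm_d / 2,
          norm_ez_reflectance = target,
          inner_amplitude = params$inner_amplitude,
          ez_amplitude = NA_real_,
          density_breakpoint = params$density_breakpoint,
          density_slow_slope = params$density_slow_slope,
          density_fast_slope = params$density_fast_slope,
          baseline_density_100 = params$baseline_density_100,
          dysflective_fraction = params$dysflective_fraction,
          sparse_survival = params$sparse_survival,
          transition_width = params$transition_width,
          mosaic_jitter_frac = params$mosaic_jitter_frac,
          axial_length = al[e],
          age = ages[i],
          bcva = bcva[e],
          params = params,
          seed = sample.int(2^20, 1)
        ), class = "degeneration_truth")
        truth$ez_amplitude <- calibrate_ez_amplitude(truth, config)
        eyes[[2 * (i - 1) + e]] <- truth
      }
      subj_rows[[i]] <- data.frame(
        subject_id = sid, sex = sample(c("F", "M"), 1), age = ages[i],
        phenotype = sample(c("USH2", "NSRP"), 1, prob = c(0.875, 0.125)),
        variant1_cdna = "c.0A>T", variant1_protein = "p.?",
        variant2_cdna = "c.0A>T", variant2_protein = "p.?",
        axial_length_od = al[1], axial_length_os = al[2],
        bcva_od = bcva[1], bcva_os = bcva[2],
        stringsAsFactors = FALSE)
    }
    subjects <- do.call(rbind, subj_rows)
    class(subjects) <- c("cohort_table", "data.frame")
    structure(list(eyes = eyes, subjects = subjects, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d eyes (seed %d)\n",
              nrow(x$subjects), length(x$eyes), x$seed))
  invisible(x)
}

#' Ground-truth biomarker record for one eye
#'
#' Returns the injected values every measurement stage is judged against:
#' ring diameters, band widths and mosaic diameter (twice the respective
#' radii), the analytic normalised EZ reflectance of the rendered band model
#' (including lateral truncation of the EZ over the 1000-um profile window),
#' and the biphasic foveal cone density.
#'
#' @param truth a `degeneration_truth` from [sample_cohort()].
#' @param config the [render_config()] used for rendering.
#' @return One-row `data.frame` of truth biomarkers.
#' @export
truth_biomarkers <- function(truth, config = render_config()) {
  stopifnot(inherits(truth, "degeneration_truth"))
  data.frame(
    eye_id = truth$eye_id,
    subject_id = truth$subject_id,
    eye = truth$eye,
    ir_diameter_um = 2 * truth$r_ir,
    or_diameter_um = 2 * truth$r_or,
    ez_width_um = 2 * truth$r_ez,
    elm_width_um = 2 * truth$r_elm,
    impm_diameter_um = 2 * truth$r_impm,
    norm_ez_reflectance = analytic_norm_reflectance(truth, config),
    cone_density_mm2 = foveal_density_truth(truth$r_ez, truth$params),
    age = truth$age,
    bcva = truth$bcva,
    axial_length = truth$axial_length,
    stringsAsFactors = FALSE)
}

#' Write / read a degeneration truth as JSON
#'
#' Serialises one eye's ground truth (geometry, density model, seed) so a
#' rendered data set can ship with its generating parameters.
#'
#' @param truth a `degeneration_truth`.
#' @param path output JSON path.
#' @return `write_truth_json()` returns `path` invisibly;
#'   `read_truth_json()` returns a `degeneration_truth`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "degeneration_truth"))
  x <- unclass(truth)
  x$params <- unclass(x$params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$params <- structure(x$params, class = "truth_params")
  x$seed <- as.integer(x$seed)
  structure(x, class = "degeneration_truth")
}

# ---- analytic OCT band model -----------------------------------------------
# The noiseless longitudinal reflectivity profile over the 1000-um window is
# a sum of depth Gaussians plus constant background, with the EZ (and ELM)
# amplitude scaled by the mean lateral taper over the window.  These
# closed-form helpers are independent of the image-processing measurement
# path and serve as its oracle.

# mean of the lateral truncation taper over |x| <= half_window
.mean_taper <- function(r, half_window, edge_sigma) {
  xs <- seq(0, half_window, by = 1)
  mean(1 - smooth_step(xs, r, edge_sigma))
}

# band amplitudes effective within the LRP window for one eye
.effective_amplitudes <- function(truth, config) {
  amp <- config$oct_band_amplitude
  amp["EZ"] <- truth$ez_amplitude
  amp[c("RNFL", "INL")] <- truth$inner_amplitude
  amp["EZ"] <- amp["EZ"] * .mean_taper(truth$r_ez, 500, config$oct_edge_sigma)
  amp["ELM"] <- amp["ELM"] * .mean_taper(truth$r_elm, 500, config$oct_edge_sigma)
  # IZ persists only where the EZ does
  amp["IZ"] <- amp["IZ"] * .mean_taper(truth$r_ez, 500, config$oct_edge_sigma)
  amp
}

.analytic_profile <- function(depths, amplitudes, config) {
  z <- depths
  prof <- rep(config$oct_background, length(z))
  for (b in names(config$oct_band_depth_um)) {
    prof <- prof + amplitudes[[b]] *
      exp(-(z - config$oct_band_depth_um[[b]])^2 /
            (2 * config$oct_band_sigma_um[[b]]^2))
  }
  prof
}

# Depth-band sampling grids for the reflectance ratio.  The ratio is
# defined on the sampled reflectivity profile, so the analytic oracle
# evaluates the band model on the same axial row grid as the rendered scan
# (but stays independent of the image-processing measurement path).
.ratio_grids <- function(config) {
  step <- config$pixel_scale_oct_axial
  rows <- seq(step, config$oct_depth_um, by = step)
  sig <- config$oct_band_sigma_um[["EZ"]]
  z_ez <- config$oct_band_depth_um[["EZ"]]
  half_w <- sig * sqrt(2 * log(2))
  z_rnfl <- rows[which.min(abs(rows - config$oct_band_depth_um[["RNFL"]]))]
  z_inl <- rows[which.min(abs(rows - config$oct_band_depth_um[["INL"]]))]
  list(num = rows[abs(rows - z_ez) <= half_w],
       den = rows[rows >= z_rnfl & rows <= z_inl])
}

# Normalised EZ reflectance of the analytic profile: mean reflectance over
# the half-maximum depth band of the EZ Gaussian divided by the mean over the
# closed depth span from the RNFL peak to the INL peak.
.analytic_ratio_from_amp <- function(amplitudes, config) {
  g <- .ratio_grids(config)
  mean(.analytic_profile(g$num, amplitudes, config)) /
    mean(.analytic_profile(g$den, amplitudes, config))
}

#' Analytic normalised EZ reflectance of a truth eye
#'
#' @param truth a `degeneration_truth`.
#' @param config a [render_config()].
#' @return the ratio of mean EZ-band reflectance (half-maximum depth band) to
#'   mean inner retinal reflectance (RNFL-to-INL depth span) of the noiseless
#'   band model.
#' @export
analytic_norm_reflectance <- function(truth, config = render_config()) {
  .analytic_ratio_from_amp(.effective_amplitudes(truth, config), config)
}

# Solve for the rendered EZ peak amplitude such that the analytic ratio of
# the untruncated profile equals the eye's normalised-reflectance target.
# The ratio is affine in A_ez: ratio(A) = (a A + b) / (c A + d).
calibrate_ez_amplitude <- function(truth, config) {
  amp0 <- config$oct_band_amplitude
  amp0[c("RNFL", "INL")] <- truth$inner_amplitude
  amp0["EZ"] <- 0
  amp1 <- amp0
  amp1["EZ"] <- 1
  g <- .ratio_grids(config)
  b <- mean(.analytic_profile(g$num, amp0, config))
  a <- mean(.analytic_profile(g$num, amp1, config)) - b
  d <- mean(.analytic_profile(g$den, amp0, config))
  cc <- mean(.analytic_profile(g$den, amp1, config)) - d
  t <- truth$norm_ez_reflectance
  A <- (t * d - b) / (a - t * cc)
  if (!is.finite(A) || A <= 0)
    stopf("cannot calibrate EZ amplitude for target ratio %.3g", t)
  A
}
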