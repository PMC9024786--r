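# Shared fixtures: a fast rendering configuration for tests that do not
# need the full-size fields, and a deterministic single-eye truth builder.

fast_config <- function(...) {
  render_config(aoslo_width_um = 3000, aoslo_height_um = 260, ...)
}

# a degeneration truth with exactly chosen radii (diameters = 2x)
make_truth <- function(r_ez = 1077.5, r_elm = 1437, r_ir = 1176,
                       r_or = 1736, r_impm = 1377,
                       norm_reflectance = 5.79, seed = 42L,
                       params = truth_params(), config = render_config(),
                       sparse_survival = params$sparse_survival,
                       dysflective_fraction = params$dysflective_fraction) {
  truth <- structure(list(
    eye_id = "T01_OD", subject_id = "T01", eye = "OD",
    r_ez = r_ez, r_elm = r_elm, r_ir = r_ir, r_or = r_or, r_impm = r_impm,
    norm_ez_reflectance = norm_reflectance,
    inner_amplitude = params$inner_amplitude,
    ez_amplitude = NA_real_,
    density_breakpoint = params$density_breakpoint,
    density_slow_slope = params$density_slow_slope,
    density_fast_slope = params$density_fast_slope,
    baseline_density_100 = params$baseline_density_100,
    dysflective_fraction = dysflective_fraction,
    sparse_survival = sparse_survival,
    transition_width = params$transition_width,
    mosaic_jitter_frac = params$mosaic_jitter_frac,
    axial_length = 24, age = 35, bcva = 0.8,
    params = params, seed = as.integer(seed)
  ), class = "degeneration_truth")
  truth$ez_amplitude <- retimetrics:::calibrate_ez_amplitude(truth, config)
  truth
}

table1_path <- function() {
  system.file("extdata", "table1.csv", package = "retimetrics")
}
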