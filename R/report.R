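# Cohort-level biomarker report: per-subject averaging, age/BCVA
# correlations, cross-modality agreement and the density relationships.

#' Cross-modality biomarker report
#'
#' Combines paired eyes per metric (mean of the available eye values), then
#' assembles the statistical surface of the analysis:
#' \describe{
#'   \item{age_bcva}{each metric against age and against BCVA
#'     (R^2, p, OLS line).}
#'   \item{cross_modality}{the spatially matched pairs - inner ring vs EZ
#'     width, outer ring vs ELM width, EZ width vs intact-mosaic diameter,
#'     inner ring vs intact-mosaic diameter - with correlation and
#'     mean-difference agreement.}
#'   \item{density}{biphasic (hinge) fits of cone density on EZ width and on
#'     inner-ring diameter, and the linear association of normalised EZ
#'     reflectance with cone density.}
#' }
#' Subjects missing a metric are excluded pairwise and each row reports the
#' n actually used; rows with fewer than 3 complete pairs carry `NA`
#' statistics and a note.
#'
#' @param biomarkers per-eye biomarker data frame with columns `subject_id`
#'   and the metrics `ir_diameter_um`, `or_diameter_um`, `ez_width_um`,
#'   `elm_width_um`, `norm_ez_reflectance`, `cone_density_mm2`,
#'   `impm_diameter_um` (`NA` for excluded/unmeasurable eyes).
#' @param cohort a `cohort_table` (or any data frame with `subject_id`,
#'   `age`, `bcva_od`, `bcva_os`).
#' @param grid_step breakpoint grid step for the hinge fits (um).
#' @param per_eye sensitivity-analysis mode: when `TRUE`, every eye enters
#'   the statistics as its own row instead of being averaged with its
#'   fellow eye (age and BCVA remain subject-level).  The default `FALSE`
#'   averages paired eyes first, since fellow eyes are not independent
#'   samples.
#' @return A list of class `biomarker_report` with the three tables and the
#'   per-subject metric table `subject_metrics`.
#' @export
biomarker_report <- function(biomarkers, cohort, grid_step = 25,
                             per_eye = FALSE) {
  metrics <- c("ir_diameter_um", "or_diameter_um", "ez_width_um",
               "elm_width_um", "norm_ez_reflectance", "cone_density_mm2",
               "impm_diameter_um")
  missing_m <- setdiff(metrics, names(biomarkers))
  if (length(missing_m))
    stopf("biomarkers lack column(s): %s", paste(missing_m, collapse = ", "))

  if (per_eye) {
    per_subject <- biomarkers[, c("subject_id", metrics)]
  } else {
    ids <- unique(biomarkers$subject_id)
    per_subject <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
    for (m in metrics) {
      per_subject[[m]] <- vapply(ids, function(id) {
        v <- biomarkers[[m]][biomarkers$subject_id == id]
        v <- v[is.finite(v)]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    }
  }
  ci <- match(per_subject$subject_id, cohort$subject_id)
  per_subject$age <- cohort$age[ci]
  per_subject$bcva <- combine_paired_eyes(cohort$bcva_od[ci],
                                          cohort$bcva_os[ci])

  safe_cor <- function(x, y) {
    res <- tryCatch(pearson_r2(x, y), error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(n = sum(is.finite(x) & is.finite(y)),
                        r_squared = NA_real_, p_value = NA_real_,
                        slope = NA_real_, intercept = NA_real_,
                        note = conditionMessage(res)))
    data.frame(n = res$n, r_squared = res$r_squared, p_value = res$p_value,
               slope = res$slope, intercept = res$intercept, note = "")
  }

  # (i) metric vs age and vs BCVA
  age_bcva <- do.call(rbind, lapply(metrics, function(m) {
    rbind(cbind(metric = m, against = "age",
                safe_cor(per_subject$age, per_subject[[m]])),
          cbind(metric = m, against = "bcva",
                safe_cor(per_subject$bcva, per_subject[[m]])))
  }))

  # (ii) cross-modality agreement pairs
  pairs <- list(
    c("ir_diameter_um", "ez_width_um"),
    c("or_diameter_um", "elm_width_um"),
    c("ez_width_um", "impm_diameter_um"),
    c("ir_diameter_um", "impm_diameter_um"))
  cross_modality <- do.call(rbind, lapply(pairs, function(p) {
    a <- per_subject[[p[1]]]; b <- per_subject[[p[2]]]
    cr <- safe_cor(a, b)
    agr <- tryCatch(mean_difference(a, b), error = function(e) NULL)
    cbind(data.frame(metric_a = p[1], metric_b = p[2]), cr,
          data.frame(
            mean_difference = if (is.null(agr)) NA_real_
                              else agr$mean_difference,
            sd_difference = if (is.null(agr)) NA_real_
                            else agr$sd_difference))
  }))

  # (iii) density relationships
  hinge <- function(m) {
    f <- tryCatch(fit_biphasic(per_subject[[m]],
                               per_subject$cone_density_mm2,
                               grid_step = grid_step),
                  error = function(e) NULL)
    if (is.null(f))
      return(data.frame(metric = m, n = NA_integer_, breakpoint = NA_real_,
                        slope_below = NA_real_, slope_above = NA_real_,
                        sse_ratio = NA_real_, unstable = NA))
    data.frame(metric = m, n = f$n, breakpoint = f$breakpoint,
               slope_below = f$slope_below, slope_above = f$slope_above,
               sse_ratio = f$sse_piecewise / f$sse_linear,
               unstable = f$unstable)
  }
  density <- list(
    ez_hinge = hinge("ez_width_um"),
    ir_hinge = hinge("ir_diameter_um"),
    reflectance_linear = cbind(
      data.frame(metric = "norm_ez_reflectance"),
      safe_cor(per_subject$norm_ez_reflectance,
               per_subject$cone_density_mm2)))

  structure(list(subject_metrics = per_subject, age_bcva = age_bcva,
                 cross_modality = cross_modality, density = density),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("Biomarker report -", nrow(x$subject_metrics), "subjects\n\n")
  cat("Cross-modality agreement (per-subject means):\n")
  cm <- x$cross_modality
  for (i in seq_len(nrow(cm)))
    cat(sprintf("  %-16s vs %-18s R^2 = %.3f  diff = %+.0f +/- %.0f (n = %d)\n",
                cm$metric_a[i], cm$metric_b[i], cm$r_squared[i],
                cm$mean_difference[i], cm$sd_difference[i], cm$n[i]))
  cat(sprintf("\nHinge fit, cone density vs EZ width: breakpoint %.0f um%s\n",
              x$density$ez_hinge$breakpoint,
              if (isTRUE(x$density$ez_hinge$unstable)) " (unstable)" else ""))
  invisible(x)
}
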