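# Cohort table input, acuity conversion and demographic summaries.

.cohort_required_cols <- c(
  "subject_id", "sex", "age", "phenotype",
  "variant1_cdna", "variant1_protein", "variant2_cdna", "variant2_protein",
  "axial_length_od", "axial_length_os", "bcva_od", "bcva_os")

#' Read and validate a cohort table
#'
#' Reads a CSV of subject records (demographics, the two disease-allele
#' variants, per-eye axial length in mm and per-eye best-corrected visual
#' acuity in Snellen decimal) and validates every record.  The packaged
#' example table is available via
#' `system.file("extdata", "table1.csv", package = "retimetrics")`.
#'
#' Validation enforces: unique subject identifiers, positive integer age,
#' axial lengths in \[20, 30\] mm, BCVA in (0, 2\], sex in \{F, M\} and
#' phenotype in \{USH2, NSRP\}.  An optional `sibling_group` column is kept
#' but never used in statistics.
#'
#' @param path path to a CSV file with a header row containing at least the
#'   columns `subject_id, sex, age, phenotype, variant1_cdna,
#'   variant1_protein, variant2_cdna, variant2_protein, axial_length_od,
#'   axial_length_os, bcva_od, bcva_os`.
#' @return A `data.frame` with class `cohort_table`, row order preserved.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (nrow(tab) == 0) stopf("no records in cohort file %s", path)
  missing_cols <- setdiff(.cohort_required_cols, names(tab))
  if (length(missing_cols))
    stopf("missing column(s): %s", paste(missing_cols, collapse = ", "))

  num_cols <- c("age", "axial_length_od", "axial_length_os",
                "bcva_od", "bcva_os")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v) & nzchar(tab[[cc]]))
    if (length(bad))
      stopf("unparsable numeric value '%s' in column %s (row %s)",
            tab[[cc]][bad[1]], cc, tab$subject_id[bad[1]])
    tab[[cc]] <- v
  }

  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup))
    stopf("duplicate subject_id: %s", paste(unique(dup), collapse = ", "))
  if (any(is.na(tab$age) | tab$age <= 0 | tab$age != round(tab$age)))
    stopf("age must be a positive integer (row %s)",
          tab$subject_id[which(is.na(tab$age) | tab$age <= 0)[1]])
  al <- c(tab$axial_length_od, tab$axial_length_os)
  if (any(is.na(al) | al < 20 | al > 30))
    stopf("axial length outside [20, 30] mm (row %s)",
          rep(tab$subject_id, 2)[which(is.na(al) | al < 20 | al > 30)[1]])
  bv <- c(tab$bcva_od, tab$bcva_os)
  if (any(is.na(bv) | bv <= 0 | bv > 2))
    stopf("BCVA outside (0, 2] (row %s)",
          rep(tab$subject_id, 2)[which(is.na(bv) | bv <= 0 | bv > 2)[1]])
  if (any(!tab$sex %in% c("F", "M")))
    stopf("sex must be F or M (row %s)",
          tab$subject_id[which(!tab$sex %in% c("F", "M"))[1]])
  if (any(!tab$phenotype %in% c("USH2", "NSRP")))
    stopf("phenotype must be USH2 or NSRP (row %s)",
          tab$subject_id[which(!tab$phenotype %in% c("USH2", "NSRP"))[1]])

  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Convert logMAR acuity to Snellen decimal
#'
#' Snellen decimal acuity is `10^(-logMAR)`; rounding belongs to the
#' reporting layer, not here.
#'
#' @param logmar numeric vector of logMAR values (finite).
#' @return Snellen decimal acuities.
#' @examples
#' snellen_decimal_from_logmar(c(0, 1, 0.48))
#' @export
snellen_decimal_from_logmar <- function(logmar) {
  if (any(!is.finite(logmar))) stopf("logMAR values must be finite")
  10^(-logmar)
}

#' Combine paired-eye values into one per-subject value
#'
#' Eyes of one subject are not independent samples, so a per-subject value is
#' the arithmetic mean of the available eye values; a single available eye
#' passes through unchanged.  `NA` marks an absent eye.  Vectorised over
#' subjects.
#'
#' @param value_od,value_os numeric vectors of per-eye values (`NA` = absent).
#' @return numeric vector of per-subject values.
#' @export
combine_paired_eyes <- function(value_od, value_os) {
  if (length(value_od) != length(value_os))
    stopf("value_od and value_os must have equal length")
  both_absent <- is.na(value_od) & is.na(value_os)
  if (any(both_absent))
    stopf("both eyes absent for element(s) %s",
          paste(which(both_absent), collapse = ", "))
  rowMeans(cbind(value_od, value_os), na.rm = TRUE)
}

#' Summary statistics of a metric
#'
#' @param values numeric vector, `NA` removed; at least one value required.
#' @return A list of class `summary_stats` with elements `n`, `mean`, `sd`
#'   (sample standard deviation, `n - 1` denominator; `NA` with a warning for
#'   `n = 1`), `min` and `max`.
#' @export
summary_stats <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stopf("no values to summarise")
  s <- if (n >= 2) stats::sd(values) else {
    warnf("sd undefined for n = 1")
    NA_real_
  }
  structure(list(n = n, mean = mean(values), sd = s,
                 min = min(values), max = max(values)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d  mean = %.4g +/- %.4g (sample SD)  range = [%.4g, %.4g]\n",
              x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Count subjects carrying a given cDNA variant
#'
#' A subject carries the variant if either allele matches the query after
#' whitespace removal (exact HGVS string match otherwise).
#'
#' @param cohort a [read_subject_table()] result.
#' @param cdna non-empty HGVS c. string, e.g. `"c.2299delG"`.
#' @return integer count of carrier subjects.
#' @export
count_variant_carriers <- function(cohort, cdna) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!is.character(cdna) || length(cdna) != 1 || !nzchar(trimws(cdna)))
    stopf("cdna must be a non-empty string")
  norm <- function(x) gsub("[[:space:]]+", "", x)
  q <- norm(cdna)
  sum(norm(cohort$variant1_cdna) == q | norm(cohort$variant2_cdna) == q)
}
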