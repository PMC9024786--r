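#' Retinal image container
#'
#' A light-weight container for one 2-D retinal image frame: the intensity
#' grid, its pixel scale(s) in micrometres per pixel, the fovea position in
#' pixel coordinates and bookkeeping flags.  Rows of `grid` run along the
#' vertical/axial direction, columns along the horizontal/lateral direction;
#' `fovea` is `c(x = column, y = row)`.
#'
#' @param grid numeric matrix of non-negative, finite intensities.
#' @param pixel_scale lateral pixel scale, micrometres per pixel.
#' @param fovea fovea position `c(x, y)` in pixels (column, row).
#' @param modality one of `"faf"`, `"oct"`, `"confocal"`, `"split_detection"`.
#' @param scale_flag intensity scale, `"linear"` or `"log"` (display scale);
#'   only meaningful for OCT B-scans.
#' @param pixel_scale_axial axial (depth) pixel scale for OCT B-scans,
#'   micrometres per pixel; defaults to `pixel_scale`.
#' @param eye_id free-text identifier carried through to reports.
#' @return An object of class `retina_image`.
#' @export
retina_image <- function(grid, pixel_scale, fovea,
                         modality = c("faf", "oct", "confocal", "split_detection"),
                         scale_flag = c("linear", "log"),
                         pixel_scale_axial = NULL,
                         eye_id = "eye") {
  modality <- match.arg(modality)
  scale_flag <- match.arg(scale_flag)
  if (!is.matrix(grid) || !is.numeric(grid))
    stopf("grid must be a numeric matrix")
  if (any(!is.finite(grid)) || any(grid < 0))
    stopf("image intensities must be finite and non-negative")
  if (!is.numeric(pixel_scale) || pixel_scale <= 0)
    stopf("pixel_scale must be a positive number (um/px)")
  fovea <- as.numeric(fovea)
  if (length(fovea) != 2 || fovea[1] < 1 || fovea[1] > ncol(grid) ||
      fovea[2] < 1 || fovea[2] > nrow(grid))
    stopf("fovea (x = %.1f, y = %.1f) lies outside the %d x %d grid",
          fovea[1], fovea[2], ncol(grid), nrow(grid))
  structure(list(
    grid = grid,
    pixel_scale = pixel_scale,
    pixel_scale_axial = if (is.null(pixel_scale_axial)) pixel_scale
                        else pixel_scale_axial,
    fovea = c(x = fovea[1], y = fovea[2]),
    modality = modality,
    scale_flag = scale_flag,
    eye_id = eye_id
  ), class = "retina_image")
}

#' @export
print.retina_image <- function(x, ...) {
  cat(sprintf("<retina_image> %s  %d x %d px  (%.2f um/px%s)  scale: %s  eye: %s\n",
              x$modality, nrow(x$grid), ncol(x$grid), x$pixel_scale,
              if (x$modality == "oct")
                sprintf(", axial %.2f um/px", x$pixel_scale_axial) else "",
              x$scale_flag, x$eye_id))
  invisible(x)
}

#' Write / read a retinal image as 16-bit TIFF plus JSON sidecar
#'
#' The TIFF stores intensities scaled to the unit interval; the sidecar
#' records the normalisation constant, pixel scale(s), fovea position,
#' intensity-scale flag and modality so that `read_retina_image()` restores
#' the object losslessly up to 16-bit quantisation.
#'
#' @param image a [retina_image].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_retina_image()` returns `path` invisibly;
#'   `read_retina_image()` returns a [retina_image].
#' @export
write_retina_image <- function(image, path) {
  stopifnot(inherits(image, "retina_image"))
  mx <- max(image$grid, 1e-12)
  tiff::writeTIFF(image$grid / mx, path, bits.per.sample = 16,
                  compression = "none")
  sidecar <- list(
    pixel_scale_um = image$pixel_scale,
    pixel_scale_axial_um = image$pixel_scale_axial,
    fovea_xy_px = as.numeric(image$fovea),
    scale_flag = image$scale_flag,
    modality = image$modality,
    eye_id = image$eye_id,
    intensity_max = mx
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_retina_image
#' @export
read_retina_image <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- tiff::readTIFF(path) * side$intensity_max
  retina_image(grid,
               pixel_scale = side$pixel_scale_um,
               fovea = side$fovea_xy_px,
               modality = side$modality,
               scale_flag = side$scale_flag,
               pixel_scale_axial = side$pixel_scale_axial_um,
               eye_id = side$eye_id)
}

# x-coordinates (um, signed, fovea at 0) of the image columns.
lateral_axis_um <- function(image) {
  (seq_len(ncol(image$grid)) - image$fovea[["x"]]) * image$pixel_scale
}

# depth/vertical coordinates (um) of the image rows.
axial_axis_um <- function(image) {
  seq_len(nrow(image$grid)) * image$pixel_scale_axial
}
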