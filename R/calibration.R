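#' Pixel-size calibration
#'
#' Records how to convert pixel measurements to millimetres: either a direct
#' `mm_per_pixel`, or a field-of-view width in mm together with the image
#' width in pixels (`mm_per_pixel = fov_width_mm / image_width_px`). Exactly
#' one of the two routes must be supplied; pixels are assumed square. The
#' magnification string is carried as metadata only — stereomicroscope zoom
#' settings do not map to a universal scale table.
#'
#' @param mm_per_pixel physical pixel size in mm.
#' @param fov_width_mm field-of-view width in mm.
#' @param image_width_px image width in pixels (e.g. 2048).
#' @param magnification optional free-text metadata.
#' @return an object of class `mp_calibration`.
#' @export
calibration_spec <- function(mm_per_pixel = NULL, fov_width_mm = NULL,
                             image_width_px = NULL, magnification = NULL) {
  direct <- !is.null(mm_per_pixel)
  fov <- !is.null(fov_width_mm) || !is.null(image_width_px)
  if (direct && fov)
    stop("supply either mm_per_pixel or fov_width_mm + image_width_px, not both")
  if (!direct && !(!is.null(fov_width_mm) && !is.null(image_width_px)))
    stop("supply either mm_per_pixel or fov_width_mm + image_width_px")
  structure(list(mm_per_pixel = mm_per_pixel, fov_width_mm = fov_width_mm,
                 image_width_px = image_width_px, magnification = magnification),
            class = "mp_calibration")
}

#' Resolve the calibration to a scale factor
#'
#' @param spec an [calibration_spec()] object.
#' @return positive mm-per-pixel scalar.
#' @export
resolve_scale <- function(spec) {
  stopifnot(inherits(spec, "mp_calibration"))
  s <- if (!is.null(spec$mm_per_pixel)) spec$mm_per_pixel
       else spec$fov_width_mm / spec$image_width_px
  if (!is.finite(s) || s <= 0) stop("calibration must yield a positive mm/pixel")
  s
}

# descriptor columns by physical dimension
.linear_cols <- c("outer_len", "total_len", "d_max", "ferret_min", "ferret_max",
                  "rect_length", "rect_width", "Ra", "Rb", "fiber_length")
.area_cols <- c("F")

#' Convert a descriptor record to SI units
#'
#' Appends millimetre columns to a pixel-unit descriptor record: linear
#' descriptors are multiplied by the scale (suffix `_mm`), areas by its
#' square (suffix `_mm2`); dimensionless descriptors (circularity,
#' compactness, elongatedness) and angles are left untouched.
#'
#' @param record descriptor `data.frame` from [describe_region()] (any number
#'   of rows).
#' @param scale mm per pixel (scalar > 0), or an `mp_calibration`.
#' @return the record with `_mm` / `_mm2` columns appended.
#' @export
to_si <- function(record, scale) {
  if (inherits(scale, "mp_calibration")) scale <- resolve_scale(scale)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  for (cl in intersect(.linear_cols, names(record)))
    record[[paste0(cl, "_mm")]] <- record[[cl]] * scale
  for (cl in intersect(.area_cols, names(record)))
    record[[paste0(cl, "_mm2")]] <- record[[cl]] * scale^2
  record
}
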