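#' Threshold specification
#'
#' Bundles the fixed intensity threshold and the item polarity used to
#' binarize a grayscale image. `polarity = "dark"` marks as foreground every
#' pixel with intensity `<= th` (item darker than the filter background);
#' `polarity = "light"` marks pixels with intensity `>= th`. Both comparisons
#' are inclusive. Typical thresholds for dark items on a bright filter lie
#' between 52 and 127; the default is 127.
#'
#' @param th intensity threshold in `[0, 255]`.
#' @param polarity `"dark"` (default) or `"light"`.
#' @return an object of class `mp_threshold`.
#' @export
threshold_spec <- function(th = 127, polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(th) || length(th) != 1L || is.na(th) || th < 0 || th > 255)
    stop("threshold must be a single value in [0, 255]")
  structure(list(th = th, polarity = polarity), class = "mp_threshold")
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Applies the ITU-R BT.601 luminance weights
#' \eqn{Y = 0.299 R + 0.587 G + 0.114 B}, rounding half-up to an integer in
#' `[0, 255]`. A grayscale matrix passes through unchanged (idempotent).
#'
#' @param img `H x W x 3` RGB array or `H x W` grayscale matrix, intensities
#'   on the 0--255 scale.
#' @return numeric `H x W` matrix of integer-valued intensities.
#' @export
to_grayscale <- function(img) {
  if (is.null(dim(img)) || any(dim(img) == 0L) || length(img) == 0L)
    stop("empty input")
  if (is.matrix(img)) {
    check_intensities(img)
    return(img)
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("expected an H x W x 3 RGB array or an H x W matrix")
  check_intensities(img)
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(round_half_up(y), dim(img)[1], dim(img)[2])
}

#' Crop a grayscale image
#'
#' Cuts out redundant background. Offsets are 0-based from the top-left
#' corner; the window must lie fully inside the image. The cumulative crop
#' offset is recorded in the `"offset"` attribute (`c(top, left)`) so that
#' downstream coordinates can be mapped back to the original image frame.
#'
#' @param img grayscale matrix.
#' @param top,left 0-based offsets of the window's top-left corner.
#' @param height,width window size in pixels.
#' @return the cropped matrix with an `"offset"` attribute.
#' @export
crop_image <- function(img, top, left, height, width) {
  stopifnot(is.matrix(img))
  if (height < 1 || width < 1 ||
      top < 0 || left < 0 ||
      top + height > nrow(img) || left + width > ncol(img))
    stop("crop out of bounds")
  out <- img[(top + 1):(top + height), (left + 1):(left + width), drop = FALSE]
  prev <- attr(img, "offset") %||% c(0, 0)
  attr(out, "offset") <- prev + c(top, left)
  out
}

#' Binarize a grayscale image at a fixed threshold
#'
#' Produces the binary item mask: 1 = item (region) pixel, 0 = background.
#' Dark polarity keeps intensities `<= th`, light polarity keeps `>= th`;
#' the two are dual, `threshold_mask(img, dark th)` equals
#' `threshold_mask(255 - img, light 255 - th)`.
#'
#' @param img grayscale matrix (0--255 scale).
#' @param spec an [threshold_spec()] object.
#' @return integer 0/1 matrix of the same size, with attributes
#'   `"threshold"` and `"polarity"`.
#' @export
threshold_mask <- function(img, spec = threshold_spec()) {
  stopifnot(is.matrix(img), inherits(spec, "mp_threshold"))
  m <- if (spec$polarity == "dark") img <= spec$th else img >= spec$th
  out <- matrix(as.integer(m), nrow(img), ncol(img))
  attr(out, "threshold") <- spec$th
  attr(out, "polarity") <- spec$polarity
  out
}

#' Check whether an image is thresholdable
#'
#' Reports the foreground fraction obtained at the given threshold and raises
#' a flag when it is 0 (no item found — e.g. a transparent item whose color
#' matches the filter) or exceeds `max_foreground` (typically an
#' inverted-polarity mistake or an unusable image).
#'
#' @param img grayscale matrix.
#' @param spec an [threshold_spec()] object.
#' @param max_foreground ceiling on the plausible item fraction (default 0.5).
#' @return list with `fraction`, logical `flag`, and a human-readable
#'   `reason` (`NA` when not flagged).
#' @export
contrast_report <- function(img, spec = threshold_spec(), max_foreground = 0.5) {
  mask <- threshold_mask(img, spec)
  frac <- mean(mask)
  reason <- NA_character_
  if (frac == 0) {
    reason <- "no foreground pixels: item color likely matches the background"
  } else if (frac > max_foreground) {
    reason <- sprintf("foreground fraction %.3f exceeds ceiling %.3f: check threshold/polarity",
                      frac, max_foreground)
  }
  list(fraction = frac, flag = !is.na(reason), reason = reason)
}

# round half away from zero on non-negatives = round half up, then clip
round_half_up <- function(x) pmin(pmax(floor(x + 0.5), 0), 255)

check_intensities <- function(img) {
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]; read images with read_image()")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
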