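#' Normalized central geometric moments of a region
#'
#' Computes \eqn{M_{ij} = \frac{1}{F}\sum_{(r,c)\in R}(r_0-r)^i(c_0-c)^j} for
#' the second-order moments (i, j) = (1,1), (2,0), (0,2), where F is the
#' region area and \eqn{(r_0, c_0)} its center of gravity. These determine the
#' equivalent ellipse of the region.
#'
#' @param region an `mp_region`.
#' @return list with `M11`, `M20`, `M02` (pixel^2).
#' @export
region_moments <- function(region) {
  stopifnot(inherits(region, "mp_region"))
  dr <- region$centroid[1] - region$pixels[, 1]
  dc <- region$centroid[2] - region$pixels[, 2]
  list(M11 = mean(dr * dc), M20 = mean(dr * dr), M02 = mean(dc * dc))
}

#' Equivalent-ellipse semi-axes from moments
#'
#' The ellipse with the same normalized second moments as the region has
#' semi-axes
#' \deqn{R_a = \sqrt{8\,(M_{20}+M_{02}+\sqrt{(M_{20}-M_{02})^2+4M_{11}^2})}/2}
#' and \eqn{R_b} with the inner minus sign. A continuous disk of radius r has
#' \eqn{M_{20}=M_{02}=r^2/4} and recovers \eqn{R_a=R_b=r}; a single pixel
#' gives (0, 0).
#'
#' @param m moment list from [region_moments()].
#' @return named vector `c(Ra, Rb)`, `Ra >= Rb >= 0`, in pixels.
#' @export
ellipse_axes <- function(m) {
  disc <- sqrt((m$M20 - m$M02)^2 + 4 * m$M11^2)
  ra2 <- 8 * (m$M20 + m$M02 + disc)
  rb2 <- 8 * (m$M20 + m$M02 - disc)
  if (rb2 < -1e-9) stop("invalid moments: negative radicand")
  c(Ra = sqrt(ra2) / 2, Rb = sqrt(max(rb2, 0)) / 2)
}

#' Maximum centroid-to-contour distance
#'
#' The largest Euclidean distance from the region's center of gravity to any
#' contour point, over the outer and all inner contours.
#'
#' @param region an `mp_region`.
#' @param cs its `mp_contours`.
#' @return distance in pixels.
#' @export
region_d_max <- function(region, cs) {
  stopifnot(inherits(cs, "mp_contours"))
  pts <- do.call(rbind, lapply(c(list(cs$outer), cs$inners), `[[`, "points"))
  sqrt(max((pts[, 1] - region$centroid[1])^2 + (pts[, 2] - region$centroid[2])^2))
}

#' Circularity
#'
#' \eqn{F / (d_{max}^2 \pi)}: 1 for a perfect circle, smaller for elongated
#' or perforated shapes. Digital rasterization can push the raw value
#' marginally above 1, so it is clamped to `[0, 1]` by default (flagged).
#' A single pixel (`d_max = 0`) is defined as perfectly circular.
#'
#' @param F region area in pixels.
#' @param d_max maximum centroid-to-contour distance, see [region_d_max()].
#' @param clamp clamp to `[0, 1]` (default `TRUE`).
#' @return circularity, with a `"flags"` attribute (character vector, possibly
#'   empty) naming `single_pixel` or `clamped_circularity` degeneracies.
#' @export
circularity <- function(F, d_max, clamp = TRUE) {
  stopifnot(F >= 1, d_max >= 0)
  if (d_max == 0) return(structure(1, flags = "single_pixel"))
  raw <- F / (d_max^2 * pi)
  if (clamp && raw > 1) structure(1, flags = "clamped_circularity")
  else structure(raw, flags = character(0))
}

#' Compactness
#'
#' \eqn{P^2 / (4 F \pi)} with P the total perimeter (outer plus inner
#' contours): 1 for a perfect circle, larger for elongated or perforated
#' shapes. A single pixel (P = 0) returns 0, flagged.
#'
#' @param P total perimeter in pixels, see [region_perimeter()].
#' @param F region area in pixels.
#' @return compactness, with a `"flags"` attribute as in [circularity()].
#' @export
compactness <- function(P, F) {
  stopifnot(F >= 1, P >= 0)
  if (P == 0) return(structure(0, flags = "single_pixel"))
  structure(P^2 / (4 * F * pi), flags = character(0))
}

#' Elongatedness
#'
#' Ratio of the minimum-area bounding rectangle's length to its width. A
#' degenerate rectangle (collinear region, width 0) yields `NA`, flagged.
#'
#' @param rect rectangle fit from [min_area_rect()].
#' @return length/width ratio (>= 1), with a `"flags"` attribute.
#' @export
elongatedness <- function(rect) {
  if (rect$width == 0) return(structure(NA_real_, flags = "degenerate_width"))
  structure(rect$length / rect$width, flags = character(0))
}

#' Fiber length estimate
#'
#' Half the outer contour length. The tracing cycle runs out along one side
#' of a fiber and back along the other, so halving it approximates the
#' centerline length; the item's width and end curvature make the estimate a
#' slight, non-negative overestimate, and it is not meaningful for fibers
#' coiled into internal spirals.
#'
#' @param outer_len outer contour length in pixels.
#' @return estimated fiber length in pixels.
#' @export
fiber_length <- function(outer_len) {
  stopifnot(outer_len >= 0)
  outer_len / 2
}

#' Assemble the full descriptor record for a region
#'
#' Combines region, contours, hull, rectangle fit and moments into one row of
#' shape descriptors (all in pixels). Fiber length is populated for every
#' region; whether an item is a fiber is the analyst's call.
#'
#' @param region an `mp_region`.
#' @param cs its `mp_contours` (computed if missing).
#' @param pixel_extent if `TRUE`, the convex hull is built over the four
#'   corners of every boundary pixel instead of pixel centers, adding the
#'   pixels' physical extent (about 1 px) to Feret and rectangle measures.
#' @return one-row `data.frame` with columns `F`, `outer_len`, `total_len`,
#'   `d_max`, `circularity`, `compactness`, `ferret_min`, `ferret_max`,
#'   `rect_length`, `rect_width`, `rect_angle`, `elongatedness`, `Ra`, `Rb`,
#'   `fiber_length`, `n_holes`, `flags` (semicolon-joined).
#' @export
describe_region <- function(region, cs = NULL, pixel_extent = FALSE) {
  stopifnot(inherits(region, "mp_region"))
  if (is.null(cs)) cs <- trace_contours(region)
  per <- region_perimeter(cs)
  dmax <- region_d_max(region, cs)

  hull_pts <- region$pixels
  if (pixel_extent) {
    off <- rbind(c(-0.5, -0.5), c(-0.5, 0.5), c(0.5, -0.5), c(0.5, 0.5))
    bnd <- cs$outer$points
    hull_pts <- do.call(rbind, lapply(seq_len(4), function(k)
      sweep(bnd, 2, -off[k, ])))
  }
  hull <- convex_hull(hull_pts)
  fer <- feret_diameters(hull)
  rect <- min_area_rect(hull)

  mom <- region_moments(region)
  axes <- ellipse_axes(mom)

  circ <- circularity(region$area, dmax)
  comp <- compactness(per$total_len, region$area)
  elo <- elongatedness(rect)
  flags <- unique(c(attr(circ, "flags"), attr(comp, "flags"), attr(elo, "flags")))

  data.frame(
    F = region$area,
    outer_len = per$outer_len,
    total_len = per$total_len,
    d_max = dmax,
    circularity = as.numeric(circ),
    compactness = as.numeric(comp),
    ferret_min = unname(fer["min_feret"]),
    ferret_max = unname(fer["max_feret"]),
    rect_length = rect$length,
    rect_width = rect$width,
    rect_angle = rect$angle,
    elongatedness = as.numeric(elo),
    Ra = unname(axes["Ra"]),
    Rb = unname(axes["Rb"]),
    fiber_length = fiber_length(per$outer_len),
    n_holes = length(cs$inners),
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Measure the single item in a binary mask
#'
#' Convenience wrapper: labels the mask, selects the largest region, traces
#' its contours and returns the descriptor record.
#'
#' @param mask 0/1 matrix.
#' @inheritParams describe_region
#' @return one-row descriptor `data.frame` (see [describe_region()]).
#' @export
measure_mask <- function(mask, pixel_extent = FALSE) {
  lab <- label_components(mask)
  region <- select_largest_region(lab$regions)
  describe_region(region, trace_contours(region), pixel_extent = pixel_extent)
}
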