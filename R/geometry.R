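#' Convex hull of pixel points
#'
#' Andrew's monotone-chain algorithm over pixel centers. Points are given as
#' (row, col); internally the hull is built in (x = col, y = row) coordinates
#' and returned in counterclockwise order under right-handed axes (which,
#' with rows increasing downward, appears clockwise on screen). Collinear
#' points interior to an edge are dropped. Degenerate inputs return the
#' degenerate hull: a single vertex, or the two endpoints of a collinear set.
#'
#' @param points n x 2 matrix of (row, col) coordinates (any real values).
#' @return m x 2 matrix of hull vertices (row, col), class `mp_hull`.
#' @export
convex_hull <- function(points) {
  if (is.null(points) || nrow(points) == 0L) stop("empty point set")
  pts <- unique(points[, c(1, 2), drop = FALSE])
  x <- pts[, 2]; y <- pts[, 1]
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  if (n == 1L) return(as_hull(cbind(y, x)))
  cross <- function(o, a, b)
    (x[a] - x[o]) * (y[b] - y[o]) - (y[a] - y[o]) * (x[b] - x[o])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(h[length(h) - 1L], h[length(h)], i) <= 0) h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  h <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(h) == 0L) h <- 1L # all points identical after unique: impossible, safety
  as_hull(cbind(y[h], x[h]))
}

as_hull <- function(m) {
  colnames(m) <- c("row", "col")
  rownames(m) <- NULL
  structure(m, class = c("mp_hull", "matrix"))
}

hull_xy <- function(h) cbind(x = h[, 2], y = h[, 1])

#' Minimum and maximum Feret diameters
#'
#' The Feret diameter along a direction is the distance between the two
#' parallel supporting lines perpendicular to it. The maximum Feret is found
#' by rotating calipers over the antipodal vertex pairs of the convex hull;
#' the minimum Feret is the smallest width over hull edges (the minimal width
#' of a convex polygon is always attained perpendicular to one of its edges).
#' Degenerate cases: a single point gives `(0, 0)`; a collinear segment gives
#' `(0, length)`.
#'
#' @param hull an `mp_hull` from [convex_hull()].
#' @return named numeric vector `c(min_feret, max_feret)` in pixels.
#' @export
feret_diameters <- function(hull) {
  P <- hull_xy(hull)
  n <- nrow(P)
  if (n == 1L) return(c(min_feret = 0, max_feret = 0))
  if (n == 2L)
    return(c(min_feret = 0, max_feret = sqrt(sum((P[2, ] - P[1, ])^2))))

  # rotating calipers over antipodal pairs (Shamos): for each edge advance the
  # opposite vertex while the supported triangle area keeps growing
  nxt <- c(2:n, 1L)
  area2 <- function(i, j, k)
    (P[j, 1] - P[i, 1]) * (P[k, 2] - P[i, 2]) -
    (P[k, 1] - P[i, 1]) * (P[j, 2] - P[i, 2])
  dmax <- 0
  j <- 2L
  for (i in seq_len(n)) {
    i1 <- nxt[i]
    while (abs(area2(i, i1, nxt[j])) > abs(area2(i, i1, j))) j <- nxt[j]
    dmax <- max(dmax,
                sum((P[i, ] - P[j, ])^2),
                sum((P[i1, ] - P[j, ])^2))
  }

  # min width: for each edge, the farthest vertex from the edge's line
  wmin <- Inf
  for (i in seq_len(n)) {
    e <- P[nxt[i], ] - P[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    d <- abs((P[, 1] - P[i, 1]) * nrm[1] + (P[, 2] - P[i, 2]) * nrm[2])
    wmin <- min(wmin, max(d))
  }
  c(min_feret = wmin, max_feret = sqrt(dmax))
}

#' Minimum-area bounding rectangle
#'
#' Rotating-calipers scan: the optimal rectangle has one side collinear with
#' a hull edge, so every edge direction is tried and the one with the
#' smallest area wins (ties broken by the smaller angle). `length` is the
#' longer side, `width` the shorter; `angle` is the orientation of the long
#' side in degrees from the column axis, in `[0, 180)`. Collinear point sets
#' yield `width = 0`.
#'
#' @param hull an `mp_hull` from [convex_hull()].
#' @return list with `center` (row, col), `length`, `width` (pixels),
#'   `angle` (degrees) and `area`.
#' @export
min_area_rect <- function(hull) {
  P <- hull_xy(hull)
  n <- nrow(P)
  if (n == 1L)
    return(list(center = c(row = P[1, 2], col = P[1, 1]),
                length = 0, width = 0, angle = 0, area = 0))
  if (n == 2L) {
    d <- P[2, ] - P[1, ]
    mid <- colMeans(P)
    return(list(center = c(row = mid[2], col = mid[1]),
                length = sqrt(sum(d^2)), width = 0,
                angle = angle_deg(d), area = 0))
  }
  nxt <- c(2:n, 1L)
  best <- NULL
  for (i in seq_len(n)) {
    e <- P[nxt[i], ] - P[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- P[, 1] * u[1] + P[, 2] * u[2]
    pv <- P[, 1] * v[1] + P[, 2] * v[2]
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    area <- du * dv
    long <- if (du >= dv) u else v
    ang <- angle_deg(long)
    cen_xy <- (min(pu) + max(pu)) / 2 * u + (min(pv) + max(pv)) / 2 * v
    cand <- list(center = c(row = unname(cen_xy[2]), col = unname(cen_xy[1])),
                 length = max(du, dv), width = min(du, dv),
                 angle = ang, area = area)
    if (is.null(best) || area < best$area - 1e-9 ||
        (abs(area - best$area) <= 1e-9 && ang < best$angle))
      best <- cand
  }
  best
}

# orientation of a direction (x, y) in degrees from the column (x) axis, [0, 180)
angle_deg <- function(d) {
  a <- atan2(d[2], d[1]) * 180 / pi
  a <- a %% 180
  if (a >= 180 - 1e-9) a <- 0
  unname(a)
}
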