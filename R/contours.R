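# Moore neighborhood in clockwise order (row down, col right), starting North.
.moore <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                 ncol = 2, byrow = TRUE)

#' Trace the outer and inner contours of a region
#'
#' Moore-neighbor tracing with Jacob's stopping criterion yields the outer
#' contour: starting from the uppermost-leftmost region pixel, the 8-neighborhood
#' of the current boundary pixel is scanned clockwise from the backtrack
#' position until a region pixel is found, and tracing stops when the start
#' pixel is about to be re-left in the initial direction. Holes — 4-connected
#' background components that do not touch the image border — each contribute
#' one inner contour, traced the same way over the hole's own pixels, so a
#' one-pixel hole degenerates to a single-point contour of length 0. Every
#' contour is a closed cycle of 8-adjacent points starting at its
#' lexicographically smallest (row, col) point; inner contours carry the outer
#' contour as parent.
#'
#' @param region an `mp_region` (see [label_components()]).
#' @param mask optional 0/1 matrix to trace in; defaults to the region's own
#'   occupancy mask (other regions are ignored either way).
#' @return an object of class `mp_contours`: list with `outer` (a contour:
#'   `points` n x 2 0-based matrix, `kind`, `parent`) and `inners` (list of
#'   contours).
#' @export
trace_contours <- function(region, mask = NULL) {
  stopifnot(inherits(region, "mp_region"))
  if (region$area < 1L) stop("region is empty")
  occ <- region_mask(region)

  start <- lexico_min(region$pixels)
  outer <- list(points = moore_trace(occ, start), kind = "outer", parent = NA_integer_)

  inners <- list()
  holes <- find_holes(occ)
  for (h in holes) {
    hocc <- matrix(FALSE, nrow(occ), ncol(occ))
    hocc[h + 1L] <- TRUE
    pts <- moore_trace(hocc, lexico_min(h))
    inners[[length(inners) + 1L]] <-
      list(points = pts, kind = "inner", parent = 1L)
  }
  structure(list(outer = outer, inners = inners), class = "mp_contours")
}

# uppermost, then leftmost pixel of an n x 2 (row, col) 0-based matrix
lexico_min <- function(px) {
  i <- order(px[, 1], px[, 2])[1]
  px[i, ]
}

# 4-connected background components fully enclosed by the mask (0-based pixels)
find_holes <- function(occ) {
  bg <- matrix(as.integer(!occ), nrow(occ), ncol(occ))
  lab <- ccl_label(bg, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep <- setdiff(unique(lab[lab > 0L]), border)
  lapply(sort(keep), function(k) {
    idx <- which(lab == k)
    rc <- arrayInd(idx, dim(lab)) - 1L
    colnames(rc) <- c("row", "col")
    rc
  })
}

# Moore-neighbor boundary tracing over `occ` (logical matrix), starting at the
# uppermost-leftmost foreground pixel `start` (0-based c(row, col)). Returns a
# closed cyclic point sequence (n x 2, 0-based) without a repeated final point.
moore_trace <- function(occ, start) {
  H <- nrow(occ); W <- ncol(occ)
  inside <- function(r, c) r >= 0 && c >= 0 && r < H && c < W && occ[r + 1, c + 1]

  p <- start
  # backtrack begins at the West neighbor, background by choice of start
  bdir <- 7L # index into .moore of the backtrack relative to p (W = row 7, 0-based 6)
  pts <- matrix(start, ncol = 2)
  first_move <- NA_integer_
  cap <- 8L * (sum(occ) + 2L)
  for (step in seq_len(cap)) {
    moved <- FALSE
    for (k in 1:8) {
      j <- ((bdir - 1L + k - 1L) %% 8L) + 1L # scan clockwise after backtrack
      q <- p + .moore[j, ]
      if (inside(q[1], q[2])) {
        if (all(p == start) && !is.na(first_move) && j == first_move)
          return(close_cycle(pts)) # Jacob's criterion: initial state repeats
        if (all(p == start) && is.na(first_move)) first_move <- j
        pts <- rbind(pts, q)
        # new backtrack: the neighbor examined just before q, seen from q
        prev <- p + .moore[((j - 2L) %% 8L) + 1L, ]
        bdir <- dir_index(q, prev)
        p <- q
        moved <- TRUE
        break
      }
    }
    if (!moved) return(pts) # isolated single pixel
  }
  stop("contour tracing failed to terminate")
}

dir_index <- function(from, to) {
  d <- to - from
  which(.moore[, 1] == d[1] & .moore[, 2] == d[2])
}

# drop the duplicated closing point(s) so the cycle is implicit
close_cycle <- function(pts) {
  n <- nrow(pts)
  while (n > 1 && all(pts[n, ] == pts[1, ])) n <- n - 1L
  out <- pts[seq_len(n), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

#' Length of a closed contour
#'
#' Sums step lengths over the cyclic point sequence: steps parallel to the
#' coordinate axes count 1, diagonal steps count \eqn{\sqrt 2}. A single-point
#' contour has length 0. Consecutive points (including last-to-first) must be
#' 8-neighbors.
#'
#' @param contour a contour from [trace_contours()], or a bare n x 2 point
#'   matrix.
#' @return length in pixels.
#' @export
contour_length <- function(contour) {
  pts <- if (is.list(contour)) contour$points else contour
  n <- nrow(pts)
  if (n == 1L) return(0)
  nxt <- pts[c(2:n, 1L), , drop = FALSE]
  dr <- abs(nxt[, 1] - pts[, 1])
  dc <- abs(nxt[, 2] - pts[, 2])
  if (any(pmax(dr, dc) != 1)) stop("broken contour")
  sum(ifelse(dr + dc == 2, sqrt(2), 1))
}

#' Outer and total perimeter of a region
#'
#' The perimeter of a region is the total contour length: the outer contour
#' plus every inner (hole) contour. Fibers that fold back on themselves can
#' enclose holes, which is why the total is reported alongside the
#' outer-only length used for fiber-length estimation.
#'
#' @param cs an `mp_contours` object.
#' @return list with `outer_len` and `total_len`, in pixels.
#' @export
region_perimeter <- function(cs) {
  stopifnot(inherits(cs, "mp_contours"))
  outer_len <- contour_length(cs$outer)
  inner <- vapply(cs$inners, contour_length, numeric(1))
  list(outer_len = outer_len, total_len = outer_len + sum(inner))
}

#' Export contours as a data frame
#'
#' @param cs an `mp_contours` object.
#' @return data.frame with columns `contour_id`, `kind`, `point_index`,
#'   `row`, `col` (0-based coordinates).
#' @export
contour_table <- function(cs) {
  stopifnot(inherits(cs, "mp_contours"))
  all <- c(list(cs$outer), cs$inners)
  do.call(rbind, lapply(seq_along(all), function(i) {
    pts <- all[[i]]$points
    data.frame(contour_id = i, kind = all[[i]]$kind,
               point_index = seq_len(nrow(pts)) - 1L,
               row = pts[, 1], col = pts[, 2])
  }))
}
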