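# Shared fixtures and independent oracles for the test suite.

# build a 0/1 mask from strings, e.g. mask_from_strings("010", "111")
mask_from_strings <- function(...) {
  rows <- c(...)
  m <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  storage.mode(m) <- "integer"
  m
}

# Flood-fill oracle for connected-component labeling: the 8- (or 4-) neighbor
# pixel graph is built explicitly and partitioned with igraph's component
# search — an independent code path from the package's two-pass Union-Find.
floodfill_partition <- function(mask, connectivity = 8) {
  idx <- which(mask == 1L)
  if (length(idx) == 0L) return(integer(0))
  H <- nrow(mask)
  rc <- arrayInd(idx, dim(mask))
  id <- seq_along(idx)
  lut <- matrix(0L, nrow(mask), ncol(mask))
  lut[idx] <- id
  offs <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  else rbind(c(-1, 0), c(0, -1))
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nr <- rc[, 1] + offs[k, 1]
    nc <- rc[, 2] + offs[k, 2]
    ok <- nr >= 1 & nc >= 1 & nr <= H & nc <= ncol(mask)
    nb <- rep(0L, length(idx))
    nb[ok] <- lut[cbind(nr[ok], nc[ok])]
    sel <- nb > 0L
    edges <- rbind(edges, cbind(id[sel], nb[sel]))
  }
  if (is.null(edges)) return(id) # no adjacencies: every pixel its own region
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  comp[seq_along(idx)] # membership per foreground pixel, in raster (idx) order
}

# two labelings of the same pixels describe the same partition iff the
# label pairing is a bijection
same_partition <- function(a, b) {
  length(a) == length(b) &&
    length(unique(a)) == length(unique(b)) &&
    length(unique(paste(a, b))) == length(unique(a))
}

# O(n^3) brute-force convex hull: a point is a hull vertex iff some directed
# line through it and another point has all remaining points strictly on one side
brute_hull_vertices <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2) return(pts)
  keep <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- pts[j, ] - pts[i, ]
      s <- (pts[, 1] - pts[i, 1]) * d[2] - (pts[, 2] - pts[i, 2]) * d[1]
      if (all(s >= -1e-9) || all(s <= 1e-9)) { keep[i] <- TRUE; break }
    }
  }
  pts[keep, , drop = FALSE]
}

# rotation-scan oracle for the minimum-area bounding rectangle
rect_scan_area <- function(pts, step_deg = 0.01) {
  th <- seq(0, 90 - step_deg, by = step_deg) * pi / 180
  x <- pts[, 2]; y <- pts[, 1]
  pu <- outer(x, cos(th)) + outer(y, sin(th))
  pv <- -outer(x, sin(th)) + outer(y, cos(th))
  du <- apply(pu, 2, max) - apply(pu, 2, min)
  dv <- apply(pv, 2, max) - apply(pv, 2, min)
  min(du * dv)
}

# boundary pixels of a mask: foreground with at least one background 8-neighbor
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  any_bg <- matrix(FALSE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    any_bg <- any_bg | pad[2:(H + 1) + dr, 2:(W + 1) + dc] == 0L
  }
  which(mask == 1L & any_bg, arr.ind = TRUE) - 1L
}

lexico_min_pts <- function(px) px[order(px[, 1], px[, 2])[1], ]

centered_disk_mask <- function(radius, canvas) {
  ctr <- (canvas - 1) / 2
  sp <- shape_spec("disk", center = c(ctr, ctr), radius = radius)
  rasterize_shape(sp, canvas, canvas)$mask
}
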