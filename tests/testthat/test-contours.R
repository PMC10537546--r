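region_of <- function(mask) select_largest_region(label_components(mask)$regions)

test_that("degenerate and hand-traced contours are exact", {
  # single pixel: one-point outer contour, length 0
  cs <- trace_contours(region_of(mask_from_strings("000", "010", "000")))
  expect_equal(nrow(cs$outer$points), 1L)
  expect_length(cs$inners, 0L)
  expect_equal(contour_length(cs$outer), 0)

  # 2x2 block: 4-point cycle of unit steps
  cs <- trace_contours(region_of(mask_from_strings("0000", "0110", "0110")))
  expect_equal(nrow(cs$outer$points), 4L)
  expect_equal(contour_length(cs$outer), 4)

  # 1x3 line: out-and-back cycle of four unit steps
  cs <- trace_contours(region_of(mask_from_strings("00000", "01110", "00000")))
  expect_equal(contour_length(cs$outer), 4)
})

test_that("contours start at the lexicographically smallest point and are 8-closed", {
  set.seed(52)
  for (i in 1:20) {
    m <- matrix(0L, 15, 15)
    m[4:12, 4:12] <- as.integer(runif(81) < 0.7)
    regs <- label_components(m)$regions
    if (length(regs) == 0) next
    r <- select_largest_region(regs)
    cs <- trace_contours(r)
    pts <- cs$outer$points
    expect_equal(unname(pts[1, ]), unname(lexico_min_pts(pts)))
    n <- nrow(pts)
    if (n > 1) {
      steps <- pmax(abs(diff(rbind(pts, pts[1, ]))[, 1]),
                    abs(diff(rbind(pts, pts[1, ]))[, 2]))
      expect_true(all(steps == 1))
    }
  }
})

test_that("holes produce inner contours with the documented degenerate case", {
  # 5x5 block, center removed: outer 16 px, single-point inner contour (length 0)
  m <- matrix(0L, 7, 7); m[2:6, 2:6] <- 1L; m[4, 4] <- 0L
  cs <- trace_contours(region_of(m))
  expect_length(cs$inners, 1L)
  expect_equal(nrow(cs$inners[[1]]$points), 1L)
  expect_equal(cs$inners[[1]]$parent, 1L)
  per <- region_perimeter(cs)
  expect_equal(per$outer_len, 16)
  expect_equal(per$total_len, per$outer_len)

  # solid 5x5: no inner contour
  m2 <- matrix(0L, 7, 7); m2[2:6, 2:6] <- 1L
  cs2 <- trace_contours(region_of(m2))
  expect_length(cs2$inners, 0L)
  expect_equal(region_perimeter(cs2)$total_len, region_perimeter(cs2)$outer_len)

  # annulus: the hole's boundary adds positive length
  ring <- rasterize_shape(shape_spec("twisted_fiber", center = c(20, 20),
                                     radius = 12, fiber_width = 5), 41, 41)
  cs3 <- trace_contours(region_of(ring$mask))
  expect_gte(length(cs3$inners), 1L)
  per3 <- region_perimeter(cs3)
  expect_gt(per3$total_len, per3$outer_len)
})

test_that("contour membership matches the mask boundary", {
  set.seed(53)
  m <- centered_disk_mask(10, 25)
  m[12:13, 12:14] <- 0L # put a hole in it
  r <- region_of(m)
  cs <- trace_contours(r)
  occ <- matrix(FALSE, nrow(m), ncol(m)); occ[r$pixels + 1L] <- TRUE
  bnd <- boundary_pixels(m)
  key <- function(p) paste(p[, 1], p[, 2])
  # outer contour points are boundary region pixels
  expect_true(all(key(cs$outer$points) %in% key(bnd)))
  # inner contour points are hole pixels adjacent to the region
  for (inn in cs$inners) {
    for (i in seq_len(nrow(inn$points))) {
      p <- inn$points[i, ]
      expect_false(occ[p[1] + 1, p[2] + 1])
      nb <- expand.grid(dr = -1:1, dc = -1:1)
      touch <- any(mapply(function(dr, dc) {
        r2 <- p[1] + dr + 1; c2 <- p[2] + dc + 1
        r2 >= 1 && c2 >= 1 && r2 <= nrow(occ) && c2 <= ncol(occ) && occ[r2, c2]
      }, nb$dr, nb$dc))
      expect_true(touch)
    }
  }
})

test_that("n x n blocks have outer contour length 4(n-1)", {
  for (n in c(2, 3, 7, 12)) {
    m <- matrix(0L, n + 4, n + 4)
    m[3:(n + 2), 3:(n + 2)] <- 1L
    expect_equal(region_perimeter(trace_contours(region_of(m)))$outer_len,
                 4 * (n - 1))
  }
})

test_that("perimeter is invariant under translation and 90-degree rotation", {
  set.seed(54)
  m <- matrix(0L, 20, 26)
  m[5:15, 6:20] <- as.integer(runif(11 * 15) < 0.75)
  regs <- label_components(m)$regions
  r <- select_largest_region(regs)
  base <- region_perimeter(trace_contours(r))$total_len

  shift <- matrix(0L, 26, 30); shift[7:26, 3:28] <- m
  expect_equal(region_perimeter(trace_contours(region_of(shift)))$total_len, base)

  rot <- t(m[nrow(m):1, , drop = FALSE]) # 90-degree rotation
  expect_equal(region_perimeter(trace_contours(region_of(rot)))$total_len, base)
})

test_that("broken point sequences are rejected", {
  expect_error(contour_length(rbind(c(0, 0), c(0, 3))), "broken contour")
})
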