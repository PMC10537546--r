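region_of <- function(mask) select_largest_region(label_components(mask)$regions)

test_that("area is the pixel count, matching analytic disk area within 2%", {
  expect_equal(region_of(mask_from_strings("111", "111", "111"))$area, 9L)
  expect_equal(region_of(mask_from_strings("010"))$area, 1L)
  d <- region_of(centered_disk_mask(20, 50))
  expect_equal(d$area, pi * 20^2, tolerance = 0.02)
})

test_that("moments match hand computations and symmetry", {
  # 1x3 horizontal line: col offsets -1, 0, 1 -> M02 = 2/3
  m <- region_moments(region_of(mask_from_strings("111")))
  expect_equal(m$M02, 2 / 3)
  expect_equal(m$M20, 0)
  expect_equal(m$M11, 0)
  # single pixel: no spread
  m1 <- region_moments(region_of(mask_from_strings("1")))
  expect_equal(unlist(m1), c(M11 = 0, M20 = 0, M02 = 0))
  # symmetric shapes have zero cross-moment
  expect_equal(region_moments(region_of(centered_disk_mask(15, 41)))$M11, 0,
               tolerance = 1e-9)
  # Cauchy-Schwarz invariant on random blobs
  set.seed(71)
  for (i in 1:10) {
    mk <- matrix(as.integer(runif(225) < 0.6), 15, 15)
    if (!any(mk == 1L)) next
    mm <- region_moments(region_of(mk))
    expect_lte(mm$M11^2, mm$M20 * mm$M02 + 1e-9)
  }
})

test_that("ellipse axes recover disk and rotated-ellipse parameters within 3%", {
  expect_equal(unname(ellipse_axes(list(M11 = 0, M20 = 0, M02 = 0))), c(0, 0))
  d <- region_of(centered_disk_mask(20, 50))
  ax <- ellipse_axes(region_moments(d))
  expect_equal(unname(ax["Ra"]), 20, tolerance = 0.03)
  expect_equal(unname(ax["Rb"]), 20, tolerance = 0.03)
  for (ang in c(0, 27, 90, 133)) {
    e <- rasterize_shape(shape_spec("ellipse", center = c(50, 50),
                                    semi_axes = c(40, 10), angle = ang), 101, 101)
    ax <- ellipse_axes(region_moments(region_of(e$mask)))
    expect_equal(unname(ax["Ra"]), 40, tolerance = 0.03)
    expect_equal(unname(ax["Rb"]), 10, tolerance = 0.03)
  }
})

test_that("d_max matches hand values and the boundary brute force", {
  expect_equal(region_d_max(region_of(mask_from_strings("1")),
                            trace_contours(region_of(mask_from_strings("1")))), 0)
  m22 <- mask_from_strings("11", "11")
  r <- region_of(m22)
  expect_equal(region_d_max(r, trace_contours(r)), sqrt(0.5))
  set.seed(72)
  for (i in 1:10) {
    mk <- matrix(0L, 18, 18)
    mk[4:15, 4:15] <- as.integer(runif(144) < 0.65)
    regs <- label_components(mk)$regions
    if (!length(regs)) next
    r <- select_largest_region(regs)
    got <- region_d_max(r, trace_contours(r))
    occ <- matrix(0L, 18, 18); occ[r$pixels + 1L] <- 1L
    bnd <- boundary_pixels(occ)
    want <- sqrt(max((bnd[, 1] - r$centroid[1])^2 + (bnd[, 2] - r$centroid[2])^2))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("circularity hits the circle limit and orders shapes correctly", {
  rec <- measure_mask(centered_disk_mask(64, 160))
  raw <- rec$F / (rec$d_max^2 * pi)
  expect_equal(raw, 1, tolerance = 0.02)
  expect_lte(rec$circularity, 1)

  bar <- rasterize_shape(shape_spec("rectangle", center = c(4.5, 150.5),
                                    length = 300, width = 3), 10, 304)
  expect_lt(measure_mask(bar$mask)$circularity, 1)

  expect_equal(as.numeric(circularity(1, 0)), 1)
  expect_equal(attr(circularity(1, 0), "flags"), "single_pixel")
  expect_equal(attr(circularity(40, 3), "flags"), "clamped_circularity")
})

test_that("compactness hits the circle limit, grows with elongation and holes", {
  rec <- measure_mask(centered_disk_mask(64, 160))
  expect_equal(rec$compactness, 1, tolerance = 0.15)

  bar <- rasterize_shape(shape_spec("rectangle", center = c(4.5, 150.5),
                                    length = 300, width = 3), 10, 304)
  expect_gt(measure_mask(bar$mask)$compactness, 1)

  solid <- matrix(0L, 7, 7); solid[2:6, 2:6] <- 1L
  holed <- solid; holed[4, 4] <- 0L
  expect_gt(measure_mask(holed)$compactness, measure_mask(solid)$compactness)

  expect_equal(as.numeric(compactness(0, 1)), 0)
})

test_that("elongatedness follows the rectangle fit with degenerate flagging", {
  sq <- matrix(1L, 8, 8)
  expect_equal(measure_mask(sq)$elongatedness, 1)
  blk <- matrix(1L, 3, 20)
  expect_equal(measure_mask(blk)$elongatedness, 19 / 2)
  line <- matrix(1L, 1, 9)
  rec <- measure_mask(line)
  expect_true(is.na(rec$elongatedness))
  expect_match(rec$flags, "degenerate_width")
})

test_that("fiber length halves the outer perimeter with known 1 x N behavior", {
  line <- matrix(0L, 3, 102); line[2, 2:101] <- 1L
  rec <- measure_mask(line)
  expect_equal(rec$outer_len, 198)
  expect_equal(rec$fiber_length, 99)
  expect_equal(fiber_length(0), 0)
})

test_that("descriptor records are internally consistent on fixtures", {
  disk <- measure_mask(centered_disk_mask(30, 80))
  expect_equal(disk$circularity, 1, tolerance = 0.03)
  expect_equal(disk$compactness, 1, tolerance = 0.15)
  expect_equal(disk$elongatedness, 1, tolerance = 0.05)
  expect_gte(disk$ferret_max + 1e-9, disk$Ra) # Feret spans diameter, Ra a semi-axis
  expect_gte(disk$Ra + 1e-9, disk$Rb)
  expect_lte(disk$ferret_min, disk$ferret_max)

  fib <- rasterize_shape(shape_spec("fiber", points = rbind(c(20, 10), c(60, 90),
                                                            c(30, 150)),
                                    fiber_width = 4), 100, 170)
  frec <- measure_mask(fib$mask)
  expect_lt(frec$circularity, 0.2)
  expect_gt(frec$compactness, 5)
})

test_that("F, circularity and compactness are exactly invariant under 90-degree rotation", {
  set.seed(73)
  m <- matrix(0L, 20, 30)
  m[5:16, 4:27] <- as.integer(runif(12 * 24) < 0.7)
  a <- measure_mask(m)
  rot <- t(m[nrow(m):1, , drop = FALSE])
  b <- measure_mask(rot)
  expect_identical(a$F, b$F)
  expect_equal(a$circularity, b$circularity, tolerance = 1e-12)
  expect_equal(a$compactness, b$compactness, tolerance = 1e-12)
})

test_that("pixel-extent mode widens Feret measures by about one pixel", {
  rec0 <- measure_mask(centered_disk_mask(20, 50))
  rec1 <- measure_mask(centered_disk_mask(20, 50), pixel_extent = TRUE)
  # corner augmentation adds between 1 (axis directions) and sqrt(2) (diagonal)
  expect_gte(rec1$ferret_max - rec0$ferret_max, 0.9)
  expect_lte(rec1$ferret_max - rec0$ferret_max, sqrt(2) + 0.1)
  expect_gte(rec1$ferret_min - rec0$ferret_min, 0.9)
  expect_lte(rec1$ferret_min - rec0$ferret_min, sqrt(2) + 0.1)
})
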