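#' Synthetic shape specification
#'
#' Describes a continuous shape to rasterize as a ground-truth fixture:
#' `disk` (radius), `rectangle` (side lengths, rotation), `ellipse`
#' (semi-axes, rotation), `fiber` (open centerline polyline plus width) or
#' `twisted_fiber` (closed-loop centerline plus width, guaranteeing at least
#' one hole). Sizes are in pixels, angles in degrees from the column axis,
#' positions (row, col) with origin at the top-left pixel center.
#'
#' @param kind one of `"disk"`, `"rectangle"`, `"ellipse"`, `"fiber"`,
#'   `"twisted_fiber"`.
#' @param center shape center `c(row, col)` (disk/rectangle/ellipse;
#'   also the loop center of a default twisted fiber).
#' @param radius disk radius, or loop radius of a default twisted fiber.
#' @param length,width rectangle side lengths (`length >= width` not required).
#' @param semi_axes ellipse semi-axes `c(a, b)`.
#' @param angle rotation in degrees (rectangle/ellipse).
#' @param points fiber centerline polyline, k x 2 matrix of (row, col).
#' @param fiber_width fiber thickness in pixels.
#' @return an object of class `mp_shape`.
#' @export
shape_spec <- function(kind = c("disk", "rectangle", "ellipse", "fiber", "twisted_fiber"),
                       center = NULL, radius = NULL, length = NULL, width = NULL,
                       semi_axes = NULL, angle = 0, points = NULL,
                       fiber_width = NULL) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, center = center, radius = radius, length = length,
               width = width, semi_axes = semi_axes, angle = angle,
               points = points, fiber_width = fiber_width)
  switch(kind,
    disk = stopifnot(!is.null(center), !is.null(radius), radius > 0),
    rectangle = stopifnot(!is.null(center), !is.null(length), !is.null(width),
                          length > 0, width > 0),
    ellipse = stopifnot(!is.null(center), !is.null(semi_axes),
                        all(semi_axes > 0)),
    fiber = stopifnot(!is.null(points), nrow(points) >= 2,
                      !is.null(fiber_width), fiber_width > 0),
    twisted_fiber = {
      stopifnot(!is.null(fiber_width), fiber_width > 0)
      if (is.null(spec$points)) {
        stopifnot(!is.null(center), !is.null(radius),
                  radius > fiber_width) # loop wider than the strand: hole survives
        th <- seq(0, 2 * pi, length.out = 97L)
        spec$points <- cbind(center[1] + radius * sin(th),
                             center[2] + radius * cos(th))
      }
    }
  )
  structure(spec, class = "mp_shape")
}

#' Rasterize a shape with analytic ground truth
#'
#' A pixel belongs to the mask iff its center lies inside the continuous
#' shape (for fibers: within `fiber_width / 2` of the centerline polyline).
#' Rectangles use a half-open inclusion rule (`[-L/2, L/2)` along each side)
#' so an axis-aligned integer-sided rectangle covers exactly
#' `length x width` pixel centers. The returned ground truth carries the
#' continuous area, extents, equivalent-ellipse semi-axes (where defined) and
#' centerline arc length, for descriptor-recovery testing.
#'
#' @param spec an [shape_spec()].
#' @param canvas_h,canvas_w canvas size in pixels.
#' @return list with `mask` (0/1 integer matrix) and `truth` (list:
#'   `kind`, `true_area`, `true_length`, `true_width`, `true_axes`,
#'   `has_hole`, `true_fiber_length`).
#' @export
rasterize_shape <- function(spec, canvas_h, canvas_w) {
  stopifnot(inherits(spec, "mp_shape"), canvas_h >= 1, canvas_w >= 1)
  check_fits(spec, canvas_h, canvas_w)
  rr <- matrix(0:(canvas_h - 1), canvas_h, canvas_w)
  cc <- matrix(0:(canvas_w - 1), canvas_h, canvas_w, byrow = TRUE)

  inside <- switch(spec$kind,
    disk = {
      (rr - spec$center[1])^2 + (cc - spec$center[2])^2 <= spec$radius^2
    },
    rectangle = {
      a <- spec$angle * pi / 180
      u <- (cc - spec$center[2]) * cos(a) + (rr - spec$center[1]) * sin(a)
      v <- -(cc - spec$center[2]) * sin(a) + (rr - spec$center[1]) * cos(a)
      u >= -spec$length / 2 & u < spec$length / 2 &
        v >= -spec$width / 2 & v < spec$width / 2
    },
    ellipse = {
      a <- spec$angle * pi / 180
      u <- (cc - spec$center[2]) * cos(a) + (rr - spec$center[1]) * sin(a)
      v <- -(cc - spec$center[2]) * sin(a) + (rr - spec$center[1]) * cos(a)
      (u / spec$semi_axes[1])^2 + (v / spec$semi_axes[2])^2 <= 1
    },
    fiber = ,
    twisted_fiber = {
      dist_to_polyline(rr, cc, spec$points) <= spec$fiber_width / 2
    }
  )
  mask <- matrix(as.integer(inside), canvas_h, canvas_w)
  list(mask = mask, truth = shape_truth(spec))
}

shape_truth <- function(spec) {
  w <- spec$fiber_width
  switch(spec$kind,
    disk = list(kind = "disk", true_area = pi * spec$radius^2,
                true_length = 2 * spec$radius, true_width = 2 * spec$radius,
                true_axes = c(spec$radius, spec$radius),
                has_hole = FALSE, true_fiber_length = NA_real_),
    rectangle = {
      L <- max(spec$length, spec$width); W <- min(spec$length, spec$width)
      list(kind = "rectangle", true_area = L * W,
           true_length = L, true_width = W,
           # uniform rectangle: M20 = L^2/12 along the long side => Ra = L/sqrt(3)
           true_axes = c(L, W) / sqrt(3),
           has_hole = FALSE, true_fiber_length = NA_real_)
    },
    ellipse = {
      a <- max(spec$semi_axes); b <- min(spec$semi_axes)
      list(kind = "ellipse", true_area = pi * a * b,
           true_length = 2 * a, true_width = 2 * b,
           true_axes = c(a, b), has_hole = FALSE,
           true_fiber_length = NA_real_)
    },
    {
      len <- polyline_length(spec$points)
      list(kind = spec$kind,
           true_area = len * w + pi * (w / 2)^2, # capsule, ignoring self-overlap
           true_length = NA_real_, true_width = w,
           true_axes = c(NA_real_, NA_real_),
           has_hole = spec$kind == "twisted_fiber",
           true_fiber_length = len)
    }
  )
}

polyline_length <- function(pts) {
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

# min distance from every grid point to a polyline (vectorized per segment)
dist_to_polyline <- function(rr, cc, pts) {
  d2 <- matrix(Inf, nrow(rr), ncol(rr))
  for (i in seq_len(nrow(pts) - 1L)) {
    p <- pts[i, ]; q <- pts[i + 1L, ]
    v <- q - p
    vv <- sum(v^2)
    if (vv == 0) {
      d2 <- pmin(d2, (rr - p[1])^2 + (cc - p[2])^2)
      next
    }
    t <- pmin(pmax(((rr - p[1]) * v[1] + (cc - p[2]) * v[2]) / vv, 0), 1)
    d2 <- pmin(d2, (rr - (p[1] + t * v[1]))^2 + (cc - (p[2] + t * v[2]))^2)
  }
  sqrt(d2)
}

# analytic bounding box must fit inside the canvas
check_fits <- function(spec, H, W) {
  bb <- switch(spec$kind,
    disk = c(spec$center - spec$radius, spec$center + spec$radius),
    rectangle = {
      a <- spec$angle * pi / 180
      hr <- (abs(spec$length * sin(a)) + abs(spec$width * cos(a))) / 2
      hc <- (abs(spec$length * cos(a)) + abs(spec$width * sin(a))) / 2
      c(spec$center - c(hr, hc), spec$center + c(hr, hc))
    },
    ellipse = c(spec$center - max(spec$semi_axes),
                spec$center + max(spec$semi_axes)),
    {
      m <- spec$fiber_width / 2
      c(apply(spec$points, 2, min) - m, apply(spec$points, 2, max) + m)
    }
  )
  if (bb[1] < 0 || bb[2] < 0 || bb[3] > H - 1 || bb[4] > W - 1)
    stop("shape does not fit inside the canvas")
  invisible(TRUE)
}

#' Render a binary mask as a noisy grayscale scene
#'
#' Emulates a stereomicroscope image of one item on a uniform filter:
#' background pixels are drawn around `bg_level`, item pixels around
#' `item_level`, with i.i.d. Gaussian noise of standard deviation `noise_sd`,
#' rounded and clipped to `[0, 255]`. Deterministic for a given seed.
#'
#' @param mask 0/1 matrix.
#' @param bg_level,item_level mean background / item intensities in
#'   `[0, 255]`; must differ.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return grayscale matrix with a `"seed"` attribute.
#' @export
render_scene <- function(mask, bg_level = 200, item_level = 80, noise_sd = 0,
                         seed = NULL) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  stopifnot(bg_level >= 0, bg_level <= 255, item_level >= 0, item_level <= 255)
  if (bg_level == item_level) stop("zero contrast: bg_level equals item_level")
  base <- ifelse(mask == 1, item_level, bg_level)
  img <- with_seed(seed, base + stats::rnorm(length(base), 0, noise_sd))
  out <- matrix(round_half_up(img), nrow(mask), ncol(mask))
  attr(out, "seed") <- seed
  out
}

#' Generate a mixed synthetic population of particles and fibers
#'
#' Draws `n_particles` compact items (disks, rotated rectangles, rotated
#' ellipses in equal proportion) and `n_fibers` curved fibers (random-heading
#' polylines, 3--7 px thick), rasterizes each at the center of its own
#' canvas and renders it over a noisy bright background. Defaults state the
#' emulated world: 200 x 200 px canvases, background level 200, item level
#' 80 (a dark item on a bright filter, cleanly split by the default
#' threshold 127) and noise SD 8, leaving more than 5 sigma between the two
#' intensity populations.
#'
#' @param n_particles,n_fibers item counts (>= 0).
#' @param seed integer seed; the whole population is reproducible from it.
#' @param canvas_h,canvas_w canvas size per scene.
#' @param bg_level,item_level,noise_sd scene rendering parameters.
#' @return list of scenes, each a list with `image` (grayscale matrix),
#'   `mask` (ground-truth 0/1 matrix), `truth`, `spec`, `kind`
#'   (`"particle"`/`"fiber"`) and `id`.
#' @export
make_population <- function(n_particles, n_fibers, seed = 1,
                            canvas_h = 200, canvas_w = 200,
                            bg_level = 200, item_level = 80, noise_sd = 8) {
  stopifnot(n_particles >= 0, n_fibers >= 0)
  with_seed(seed, {
    kinds <- c(rep("particle", n_particles), rep("fiber", n_fibers))
    out <- vector("list", length(kinds))
    for (i in seq_along(kinds)) {
      spec <- if (kinds[i] == "particle")
        random_particle_spec(canvas_h, canvas_w)
      else
        random_fiber_spec(canvas_h, canvas_w)
      ras <- rasterize_shape(spec, canvas_h, canvas_w)
      img <- render_scene(ras$mask, bg_level, item_level, noise_sd)
      out[[i]] <- list(image = img, mask = ras$mask, truth = ras$truth,
                       spec = spec, kind = kinds[i],
                       id = sprintf("%s_%03d", kinds[i], i))
    }
    out
  })
}

random_particle_spec <- function(H, W) {
  kind <- sample(c("disk", "rectangle", "ellipse"), 1L)
  margin <- 3
  if (kind == "disk") {
    r <- stats::runif(1, 8, 30)
    shape_spec("disk", center = rand_center(H, W, r + margin), radius = r)
  } else if (kind == "rectangle") {
    L <- stats::runif(1, 20, 70)
    Wd <- stats::runif(1, 8, min(L, 50))
    half <- sqrt(L^2 + Wd^2) / 2
    shape_spec("rectangle", center = rand_center(H, W, half + margin),
               length = L, width = Wd, angle = stats::runif(1, 0, 180))
  } else {
    a <- stats::runif(1, 10, 40)
    b <- stats::runif(1, 5, max(5, 0.8 * a))
    shape_spec("ellipse", center = rand_center(H, W, a + margin),
               semi_axes = c(a, b), angle = stats::runif(1, 0, 180))
  }
}

rand_center <- function(H, W, clearance) {
  c(stats::runif(1, clearance, H - 1 - clearance),
    stats::runif(1, clearance, W - 1 - clearance))
}

# random-heading polyline fiber, retried until it fits the canvas
random_fiber_spec <- function(H, W) {
  for (try in 1:200) {
    w <- stats::runif(1, 3, 7)
    m <- w / 2 + 3
    p <- matrix(c(stats::runif(1, m, H - 1 - m), stats::runif(1, m, W - 1 - m)),
                ncol = 2)
    heading <- stats::runif(1, 0, 2 * pi)
    for (s in 1:5) {
      step <- stats::runif(1, 20, 45)
      heading <- heading + stats::runif(1, -0.9, 0.9)
      p <- rbind(p, p[nrow(p), ] + step * c(sin(heading), cos(heading)))
    }
    ok <- all(p[, 1] >= m & p[, 1] <= H - 1 - m &
              p[, 2] >= m & p[, 2] <= W - 1 - m)
    if (ok) return(shape_spec("fiber", points = p, fiber_width = w))
  }
  stop("could not place a fiber inside the canvas")
}

# evaluate `code` under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
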