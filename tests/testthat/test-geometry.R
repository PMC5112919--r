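test_that("closed-form shape properties match the capsule and sphere formulas", {
  caps <- cell_shape("capsule", 0.5, 2)
  p <- shape_properties(caps)
  expect_equal(p$volume, 2.0944, tolerance = 1e-4)
  expect_equal(p$surface, 9.4248, tolerance = 1e-4)
  expect_equal(p$mean_projected_area, 2.3562, tolerance = 1e-4)
  expect_equal(p$mean_chord, 0.8889, tolerance = 1e-4)
  # internal consistency of the four quantities
  expect_equal(p$mean_projected_area, p$surface / 4, tolerance = 1e-12)
  expect_equal(p$mean_chord, 4 * p$volume / p$surface, tolerance = 1e-12)

  sph_limit <- shape_properties(cell_shape("capsule", 0.5, 0))
  expect_equal(sph_limit$volume, 0.5236, tolerance = 1e-3)
  expect_equal(sph_limit$mean_projected_area, pi * 0.25, tolerance = 1e-12)

  drad <- shape_properties(cell_shape("sphere", 1.5))
  expect_equal(drad$mean_projected_area, 7.0686, tolerance = 1e-4)

  expect_error(cell_shape("capsule", -1, 2), "radius")
  expect_error(cell_shape("capsule", 0.5, -1), "cylinder_length")
})

test_that("ray-capsule chords are exact for axial, perpendicular and missing rays", {
  caps <- cell_shape("capsule", 0.5, 2)
  ax <- ray_chord(c(-5, 0, 0), c(1, 0, 0), caps, axis = c(1, 0, 0))
  expect_equal(ax$length, 3.0, tolerance = 1e-12)   # L + 2r along the axis
  perp <- ray_chord(c(-5, 0, 0), c(1, 0, 0), caps, axis = c(0, 0, 1))
  expect_equal(perp$length, 1.0, tolerance = 1e-12) # 2r through the cylinder
  miss <- ray_chord(c(-5, 0.6, 0), c(1, 0, 0), caps, axis = c(1, 0, 0))
  expect_null(miss)
  behind <- ray_chord(c(5, 0, 0), c(1, 0, 0), caps, axis = c(1, 0, 0))
  expect_null(behind)
  expect_warning(ray_chord(c(-5, 0, 0), c(2, 0, 0), caps), "normaliz")
})

test_that("random ray chords agree with a point-membership bisection oracle", {
  caps <- cell_shape("capsule", 0.5, 2)
  axis <- c(1, 1, 1) / sqrt(3)
  inside <- function(x) {
    # distance from x to the core segment vs radius
    s <- max(-1, min(1, sum((x) * axis)))
    sqrt(sum((x - s * axis)^2)) < caps$radius
  }
  set.seed(31)
  checked <- 0
  for (i in 1:200) {
    o <- rnorm(3); o <- 3 * o / sqrt(sum(o^2))      # on a radius-3 sphere
    aim <- rnorm(3) * 0.4                           # near the capsule core
    d <- aim - o; d <- d / sqrt(sum(d^2))
    ch <- ray_chord(o, d, caps, center = c(0, 0, 0), axis = axis)
    if (is.null(ch) || ch$t_entry < 0) next
    eps <- 1e-6
    expect_false(inside(o + (ch$t_entry - eps) * d))
    expect_true(inside(o + (ch$t_entry + eps) * d) ||
                  ch$length < 2 * eps)  # tangential grazing allowed
    expect_false(inside(o + (ch$t_exit + eps) * d))
    checked <- checked + 1
  }
  expect_gt(checked, 20)
})

test_that("Cauchy's formula: Monte Carlo mean projected area equals surface/4", {
  r <- 0.5; L <- 2
  set.seed(99)
  n <- 2e5
  u <- runif(n, -1, 1)            # cos(theta) of isotropic directions
  areas <- capsule_projected_area(acos(u), r, L)
  se <- sd(areas) / sqrt(n)
  expect_lt(abs(mean(areas) - shape_properties(cell_shape("capsule", r, L))$surface / 4),
            3 * se)
})

test_that("cell placement is reproducible, non-overlapping and respects density", {
  d1 <- place_cells(150, 50, seed = 5)
  d2 <- place_cells(150, 50, seed = 5)
  expect_identical(d1$centers, d2$centers)
  expect_identical(d1$orientations, d2$orientations)
  d3 <- place_cells(150, 50, seed = 6)
  expect_false(identical(d1$centers, d3$centers))

  # default domain volume fraction
  dom <- place_cells(4000, 200, seed = 1)
  pf <- 4000 * shape_properties(dom$shape)$volume / 200^3
  expect_equal(pf, 1.047e-3, tolerance = 1e-3)
  expect_true(all(dom$centers >= 0 & dom$centers < 200))
  expect_equal(sqrt(rowSums(dom$orientations^2)), rep(1, 4000), tolerance = 1e-9)

  # non-overlap: pairwise core-segment distances >= 2r (minimum image)
  sh <- d1$shape; h <- sh$cylinder_length / 2
  mind <- Inf
  for (i in 1:(d1$n - 1)) for (j in (i + 1):d1$n) {
    del <- d1$centers[j, ] - d1$centers[i, ]
    del <- del - 50 * round(del / 50)
    if (sqrt(sum(del^2)) > 2 * (sh$radius + h)) next
    dd <- microdosim:::segment_distance_cpp(d1$centers[i, ], d1$orientations[i, ], h,
                                         d1$centers[i, ] + del, d1$orientations[j, ], h)
    mind <- min(mind, dd)
  }
  expect_gte(mind, 2 * sh$radius - 1e-9)

  expect_error(place_cells(5000, 10, seed = 1), "packing")
  empty <- place_cells(0, 200, seed = 1)
  expect_equal(empty$n, 0)
})

test_that("periodic advance keeps the global position exact and wraps tiles", {
  co <- tile_coordinate(c(0L, 0L, 0L), c(190, 0, 0), edge = 200)
  co2 <- advance_periodic(co, c(20, 0, 0))
  expect_equal(co2$tile, c(1L, 0L, 0L))
  expect_equal(co2$local, c(10, 0, 0))

  expect_equal(advance_periodic(co, c(0, 0, 0))$local, co$local)

  # brute-force 1 um stepping oracle for a multi-wrap displacement
  co3 <- advance_periodic(tile_coordinate(c(0L, 0L, 0L), c(0, 0, 0), 200),
                          c(450, 0, 0))
  pos <- c(0, 0, 0); tile <- c(0, 0, 0)
  for (s in 1:450) {
    pos[1] <- pos[1] + 1
    if (pos[1] >= 200) { pos[1] <- pos[1] - 200; tile[1] <- tile[1] + 1 }
  }
  expect_equal(co3$tile, as.integer(tile))
  expect_equal(co3$local, pos)

  # global continuity under a random walk
  set.seed(8)
  co <- tile_coordinate(c(0L, 0L, 0L), c(100, 100, 100), 200)
  disp <- matrix(rnorm(300, sd = 150), ncol = 3)
  for (i in 1:100) co <- advance_periodic(co, disp[i, ])
  expect_equal(global_position(co), c(100, 100, 100) + colSums(disp),
               tolerance = 1e-9)
})

test_that("virtual-well membership terminates walked tracks at the boundary", {
  well <- list(min = c(-5000, -5000, -5000), max = c(5000, 5000, 5000))
  expect_true(in_well(c(0, 0, 0), well))
  expect_false(in_well(c(6000, 0, 0), well))
  co <- tile_coordinate(c(0L, 0L, 0L), c(0, 0, 0), 200)
  steps <- 0
  while (in_well(co, well) && steps < 100) {
    co <- advance_periodic(co, c(100, 0, 0))
    steps <- steps + 1
  }
  expect_equal(steps, 51)  # killed just past 5000 um of net displacement
})

test_that("microdomain serialization round-trips", {
  dom <- place_cells(25, 40, seed = 3)
  path <- tempfile(fileext = ".txt")
  write_microdomain(dom, path)
  back <- read_microdomain(path)
  expect_equal(back$edge, dom$edge)
  expect_equal(back$n, dom$n)
  expect_equal(back$centers, dom$centers, tolerance = 1e-9)
  expect_equal(back$orientations, dom$orientations, tolerance = 1e-9)
  expect_equal(back$shape, dom$shape)
  expect_error(read_microdomain(system.file("extdata",
    "terrestrial_gamma_spectrum.txt", package = "microdosim")), "not a")
})
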