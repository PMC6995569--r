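test_that("interior erasure leaves only the border band", {
  disk <- disk_mask(21, 21, 11, 11, 8)
  band <- erase_interior(disk)
  # oracle: erosion-based interior must be gone
  interior <- disk
  for (i in 2:20) for (j in 2:20)
    interior[i, j] <- all(disk[(i - 1):(i + 1), (j - 1):(j + 1)])
  interior[1, ] <- interior[21, ] <- interior[, 1] <- interior[, 21] <- FALSE
  expect_identical(band, disk & !interior)
  expect_false(any(band & interior))

  ring <- disk_mask(21, 21, 11, 11, 8) & !disk_mask(21, 21, 11, 11, 7)
  expect_identical(erase_interior(ring), ring)  # 1-px ring unchanged
  empty <- matrix(FALSE, 10, 10)
  expect_identical(erase_interior(empty), empty)
})

test_that("geodesic map equals the chamfer relaxation oracle", {
  # free 11x11 grid from the centre
  free <- matrix(FALSE, 11, 11)
  g <- geodesic_map(free, c(5, 5))
  expect_equal(g$distances[1, 1], 5 * sqrt(2), tolerance = 1e-12)
  expect_equal(g$distances[6, 6], 0)
  expect_equal(g$distances, geodesic_oracle(free, 5, 5), tolerance = 1e-12)

  # random barriers on small grids
  for (seed in 1:3) {
    set.seed(seed)
    b <- matrix(runif(24 * 20) < 0.25, 24, 20)
    b[13, 11] <- FALSE
    expect_equal(geodesic_map(b, c(12, 10))$distances,
                 geodesic_oracle(b, 12, 10), tolerance = 1e-12,
                 label = paste("chamfer oracle seed", seed))
  }
  expect_error(geodesic_map(matrix(TRUE, 8, 8), c(3, 3)), "border")
})

test_that("closed ring encloses; open C-shape leaks only through the gap", {
  # band of ~2 px so the barrier has no diagonal cracks
  ring <- ring_mask(41, 41, 21, 21, 11, 13)
  g <- geodesic_map(ring, c(20, 20))
  expect_true(is.infinite(g$distances[1, 1]))
  expect_true(all(is.finite(g$distances[disk_mask(41, 41, 21, 21, 10)])))

  # C-shape: same ring with a gap on the right
  cshape <- ring
  cshape[19:23, 31:41] <- FALSE
  gc <- geodesic_map(cshape, c(20, 20))
  expect_equal(gc$distances, geodesic_oracle(cshape, 20, 20), tolerance = 1e-12)
  # exterior is reachable, but only the long way round through the gap:
  # the geodesic distance to a point behind the ring exceeds the Euclidean one
  behind <- c(21, 3)  # 1-based (row 21, col 3): diametrically opposite the gap
  eucl <- sqrt((21 - 21)^2 + (3 - 21)^2)
  expect_true(is.finite(gc$distances[behind[1], behind[2]]))
  expect_gt(gc$distances[behind[1], behind[2]], 2 * eucl)
})

test_that("boundary extraction recovers a ring and rejects empty evidence", {
  ring <- ring_mask(61, 61, 31, 31, 19.5, 21.5)
  g <- geodesic_map(ring, c(30, 30))
  bd <- extract_boundary(g, rep(20L, 64))
  expect_s3_class(bd, "BoundaryCurve")
  rad <- sqrt((bd$points[, 1] - 30)^2 + (bd$points[, 2] - 30)^2)
  expect_lt(mean(abs(rad - 20)), 1.5)
  expect_null(extract_boundary(g, rep(0L, 64)))
})

test_that("traced boundary of a convex blob is closed and simple", {
  blob <- disk_mask(41, 41, 21, 19, 12)
  g <- geodesic_map(erase_interior(blob), c(20, 18))
  bd <- extract_boundary(g, rep(12L, 32))
  pts <- round(bd$points)
  # closed: consecutive points (and the wrap pair) are 8-neighbours
  steps <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  expect_true(all(abs(steps) <= 1))
  # simple: no pixel visited twice
  expect_false(any(duplicated(pts)))
})

test_that("Fourier smoothing keeps >= 98% energy, is idempotent, reduces jitter", {
  th <- 2 * pi * (0:63) / 64
  circ <- structure(list(points = cbind(row = 30 + 10 * sin(th),
                                        col = 40 + 10 * cos(th)),
                         is_closed = TRUE), class = "BoundaryCurve")
  sm <- fourier_smooth(circ)
  expect_equal(attr(sm, "n_harmonics"), 1L)
  expect_lt(max(abs(sm$points - circ$points)), 1e-9)

  set.seed(12)
  for (rep in 1:5) {
    jit <- circ
    jit$points <- jit$points + 0.5 * matrix(rnorm(128), 64, 2)
    s1 <- fourier_smooth(jit)
    expect_gte(attr(s1, "retained_energy_fraction"), 0.98)
    s2 <- fourier_smooth(s1)
    expect_lt(max(abs(s1$points - s2$points)), 1e-9)
    dev_in <- max(abs(sqrt((jit$points[, 1] - 30)^2 + (jit$points[, 2] - 40)^2) - 10))
    dev_out <- max(abs(sqrt((s1$points[, 1] - 30)^2 + (s1$points[, 2] - 40)^2) - 10))
    expect_lt(dev_out, dev_in)
  }
  open_curve <- structure(list(points = circ$points, is_closed = FALSE),
                          class = "BoundaryCurve")
  expect_error(fourier_smooth(open_curve), "closed")
})

test_that("ellipse fit recovers exact parameters and handles circles", {
  pts <- ellipse_points(32, cx = 40, cy = 60, a = 15, b = 9, theta = pi / 6)
  e <- fit_ellipse(pts, outlier_pass = FALSE)
  expect_equal(unname(e$center), c(40, 60), tolerance = 1e-6)
  expect_equal(e$a, 15, tolerance = 1e-6)
  expect_equal(e$b, 9, tolerance = 1e-6)
  expect_equal(e$angle, pi / 6, tolerance = 1e-6)

  circ <- ellipse_points(32, 40, 60, 9, 9, 0)
  ec <- fit_ellipse(circ, outlier_pass = FALSE)
  expect_equal(ec$a, ec$b, tolerance = 1e-6)
  expect_identical(ec$angle, 0)

  expect_error(fit_ellipse(pts[1:4, ]), "5 points")
  line <- cbind(row = 1:10, col = 2 * (1:10) + 1)
  expect_error(fit_ellipse(line), "collinear|ellipse")
})

test_that("ellipse fit survives gross outliers via the rejection pass", {
  pts <- ellipse_points(32, 40, 60, 15, 9, pi / 6)
  dirty <- rbind(pts, c(100, 10), c(5, 90), c(90, 90))
  e <- fit_ellipse(dirty)
  expect_lt(sqrt((e$center["cx"] - 40)^2 + (e$center["cy"] - 60)^2), 0.5)
  expect_equal(e$n_points_used, 32L)
})

test_that("ellipse fit is translation and rotation equivariant", {
  pts <- ellipse_points(40, 25, 35, 12, 7, 0.4)
  base <- fit_ellipse(pts, outlier_pass = FALSE)
  shifted <- fit_ellipse(pts + matrix(c(3.5, -2.25), 40, 2, byrow = TRUE),
                         outlier_pass = FALSE)
  expect_equal(unname(shifted$center - base$center), c(-2.25, 3.5),
               tolerance = 1e-6)
  expect_equal(shifted$a, base$a, tolerance = 1e-6)
  expect_equal(shifted$angle, base$angle, tolerance = 1e-6)

  phi <- 0.7
  # R(phi) acting on column vectors; rows of xy are rotated via %*% t(R)
  Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  xy <- cbind(pts[, 2], pts[, 1]) %*% t(Rm)     # rotate in (x, y)
  rot <- fit_ellipse(cbind(row = xy[, 2], col = xy[, 1]), outlier_pass = FALSE)
  expect_equal(rot$angle, (base$angle + phi) %% pi, tolerance = 1e-6)
  expect_equal(rot$a, base$a, tolerance = 1e-6)
  expect_equal(rot$b, base$b, tolerance = 1e-6)
})

test_that("view classification splits on the aspect threshold", {
  mk <- function(a, b) structure(list(center = c(cx = 0, cy = 0), a = a, b = b,
                                      angle = 0), class = "EllipseParams")
  expect_identical(classify_view(mk(10, 9)), "top")
  expect_identical(classify_view(mk(30, 8)), "side")
  expect_identical(classify_view(mk(15, 10)), "side")  # exactly at 1.5
})
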