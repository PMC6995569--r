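test_that("Otsu threshold equals the exhaustive between-class-variance maximizer", {
  img <- matrix(c(rep(0.2, 128), rep(0.8, 128)), 16, 16)
  o <- otsu_threshold(img)
  expect_true(all(o$binary == (img > 0.5)))
  expect_equal(o$threshold, otsu_oracle(img), tolerance = 1e-12)

  for (seed in 1:4) {
    set.seed(seed)
    rnd <- matrix(runif(400), 20, 20)
    expect_equal(otsu_threshold(rnd)$threshold, otsu_oracle(rnd),
                 tolerance = 1e-12)
  }
  # bimodal with unequal masses
  set.seed(99)
  bim <- matrix(c(rnorm(300, 0.25, 0.03), rnorm(100, 0.75, 0.03)), 20, 20)
  bim <- pmin(pmax(bim, 0), 1)
  expect_equal(otsu_threshold(bim)$threshold, otsu_oracle(bim), tolerance = 1e-12)

  const <- otsu_threshold(matrix(0.4, 8, 8))
  expect_true(const$degenerate)
  expect_false(any(const$binary))
  expect_equal(const$threshold, 0.4)
})

test_that("component labeling agrees with a flood-fill oracle for 4 and 8 connectivity", {
  # two squares sharing exactly one corner
  m <- matrix(FALSE, 30, 30)
  m[2:13, 2:13] <- TRUE
  m[14:25, 14:25] <- TRUE
  expect_equal(max(label_components(m, 8)), 1L)
  expect_equal(max(label_components(m, 4)), 2L)
  for (seed in 1:3) {
    set.seed(seed)
    rnd <- matrix(runif(225) < 0.4, 15, 15)
    for (conn in c(4L, 8L))
      expect_equal(max(label_components(rnd, conn)),
                   flood_count_oracle(rnd, conn),
                   label = sprintf("seed %d conn %d", seed, conn))
  }
})

test_that("area gate is inclusive at exactly 100 and 1500 px", {
  B <- matrix(FALSE, 120, 300)
  # areas 90, 100, 1500, 1600 as separated rectangles
  B[2:10, 2:11]    <- TRUE  # 90
  B[2:11, 30:39]   <- TRUE  # 100
  B[20:69, 60:89]  <- TRUE  # 1500
  B[20:59, 120:159] <- TRUE # 1600
  W <- matrix(0.5, 120, 300)
  cands <- extract_candidates(B, B, W, picking_config())
  expect_length(cands, 2L)
  expect_setequal(vapply(cands, `[[`, 0L, "area"), c(100L, 1500L))
  # empty binary
  expect_length(extract_candidates(B & FALSE, B & FALSE, W, picking_config()), 0L)
})

test_that("candidates are ordered by centroid and centroids are pixel means", {
  B <- matrix(FALSE, 100, 100)
  B[60:75, 10:25] <- TRUE
  B[10:25, 50:65] <- TRUE
  cands <- extract_candidates(B, B, matrix(0.5, 100, 100), picking_config())
  expect_length(cands, 2L)
  expect_equal(cands[[1]]$centroid, c(mean(10:25) - 1, mean(50:65) - 1))
  expect_equal(cands[[2]]$centroid, c(mean(60:75) - 1, mean(10:25) - 1))
  expect_true(cands[[1]]$centroid[1] < cands[[2]]$centroid[1])
})

test_that("border distances find the first positive derivative impulse", {
  # B true outside a disk of radius 20: first impulse at the disk edge
  B <- !disk_mask(101, 101, 51, 51, 20)
  rp <- radial_profiles(B, c(50, 50), picking_config())
  expect_true(all(abs(rp$border_distances - 20) <= 1))
  # all-false mask: no impulse anywhere
  none <- radial_profiles(matrix(FALSE, 64, 64), c(32, 32), picking_config())
  expect_true(all(none$border_distances == 0L))
  # hand profile [0,0,1,1,0] -> impulse at step 3
  p <- c(0, 0, 1, 1, 0)
  expect_identical(which(diff(p) > 0)[1] + 1L, 3L)
  prof_b <- matrix(FALSE, 20, 20)
  prof_b[10, 13:14] <- TRUE  # ray 1 (angle 0) hits at steps 3..4 from (9, 9)
  rp2 <- radial_profiles(prof_b, c(9, 9), picking_config(radius = 8))
  expect_identical(rp2$border_distances[1], 3L)
})

test_that("polar unwrap has the contracted shape and is angle-coherent on symmetric rings", {
  cfg <- picking_config()
  W <- matrix(0, 121, 121)
  r <- matrix(seq_len(121), 121, 121)
  c <- matrix(seq_len(121), 121, 121, byrow = TRUE)
  rad <- sqrt((r - 61)^2 + (c - 61)^2)
  W[] <- exp(-(rad - 25)^2 / 18)  # smooth rotationally symmetric ring
  g <- polar_unwrap(W, c(60, 60), cfg)
  expect_equal(dim(g), c(cfg$n_rays, cfg$radius))
  expect_lt(max(apply(g, 2, sd)), 0.1 * diff(range(W)))
  # constant image -> constant patch
  gc <- polar_unwrap(matrix(0.3, 121, 121), c(60, 60), cfg)
  expect_true(all(gc == 0.3))
})

test_that("cepstrum inverse is pure real and the score separates bands from noise", {
  cfg <- picking_config()
  band <- matrix(0, cfg$n_rays, cfg$radius); band[, 18:22] <- 1
  set.seed(4)
  noise <- matrix(runif(cfg$n_rays * cfg$radius), cfg$n_rays, cfg$radius)
  cb <- cepstrum_accept(band, cfg)
  cn <- cepstrum_accept(noise, cfg)
  expect_lt(cb$max_imag_ratio, 1e-6)
  expect_lt(cn$max_imag_ratio, 1e-6)
  expect_gt(cb$score, cn$score)
  expect_true(cb$accepted)
  # degenerate constant patch scores 0 and is rejected
  cc <- cepstrum_accept(matrix(0.7, cfg$n_rays, cfg$radius), cfg)
  expect_identical(cc$score, 0)
  expect_false(cc$accepted)
})

test_that("annulus phantom is accepted and pink-noise regions rejected", {
  cfg <- picking_config()
  m <- 256
  W <- 0.3 * (pink_noise(c(m, m), beta = 1, seed = 3) + 3) / 6
  W[ring_mask(m, m, 71, 71, 14, 20)] <- 1          # closed annular border
  ann <- cepstrum_accept(polar_unwrap(W, c(70, 70), cfg), cfg)
  expect_true(ann$accepted)
  # patches centred on the background far from the ring: no closed border
  locs <- list(c(180, 60), c(60, 180), c(180, 180), c(200, 120),
               c(120, 200), c(150, 150), c(200, 200), c(90, 190))
  noise_scores <- vapply(locs, function(p)
    cepstrum_accept(polar_unwrap(W, p, cfg), cfg)$score, 0)
  expect_true(all(noise_scores < cfg$cepstrum_accept_threshold))
  expect_gt(ann$score, max(noise_scores))
})
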