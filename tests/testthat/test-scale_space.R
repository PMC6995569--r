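test_that("normalization maps extremes to [0, 1] and flags constant input", {
  mg <- normalize_micrograph(matrix(c(0, 255), 8, 8))
  expect_equal(range(mg$pixels), c(0, 1))
  expect_false(mg$degenerate)

  set.seed(11)
  raw <- matrix(sample.int(65535, 256, replace = TRUE), 16, 16)
  nm <- normalize_micrograph(raw)
  oracle <- (raw - min(raw)) / (max(raw) - min(raw))
  expect_identical(nm$pixels, oracle)
  expect_identical(min(nm$pixels), 0)
  expect_identical(max(nm$pixels), 1)

  const <- normalize_micrograph(matrix(128, 10, 10))
  expect_true(const$degenerate)
  expect_true(all(const$pixels == 0))

  bad <- matrix(1, 8, 8); bad[3, 3] <- NaN
  expect_error(normalize_micrograph(bad), "finite")
})

test_that("Perona-Malik diffusion matches the explicit stencil oracle", {
  set.seed(21)
  img <- matrix(runif(25), 5, 5)
  expect_equal(pm_diffuse(img, K = 0.1, n_iter = 1, dt = 0.2),
               pm_step_oracle(img, K = 0.1, dt = 0.2), tolerance = 1e-12)
  # two steps = oracle applied twice
  expect_equal(pm_diffuse(img, K = 0.05, n_iter = 2, dt = 0.15),
               pm_step_oracle(pm_step_oracle(img, 0.05, 0.15), 0.05, 0.15),
               tolerance = 1e-12)
})

test_that("PM diffusion is identity on constants, conserves mass, keeps range", {
  const <- matrix(0.37, 12, 9)
  expect_identical(pm_diffuse(const, 0.05, 25), const)
  for (seed in 1:3) {
    set.seed(seed)
    img <- matrix(runif(32 * 24), 32, 24)
    out <- pm_diffuse(img, K = 0.05, n_iter = 10)
    expect_lt(abs(sum(out) - sum(img)) / sum(img), 1e-6)
    expect_gte(min(out), min(img) - 1e-12)
    expect_lte(max(out), max(img) + 1e-12)
  }
  expect_error(pm_diffuse(const, 0.05, 5, dt = 0.3), "stability")
  expect_error(pm_diffuse(const, 0.05, 5, dt = 0), "stability")
})

test_that("Gaussian blur: identity at sigma 0, impulse reproduces the kernel, mean preserved", {
  set.seed(5)
  img <- matrix(runif(30 * 40), 30, 40)
  expect_identical(gaussian_blur(img, 0), img)
  expect_lt(abs(mean(gaussian_blur(img, 2.7)) - mean(img)), 1e-6)

  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  out <- gaussian_blur(imp, 1)
  off <- (-4):4
  k1 <- exp(-off^2 / 2); k1 <- k1 / sum(k1)
  expect_equal(out[17 + off, 17 + off], outer(k1, k1), tolerance = 1e-12)
  expect_error(gaussian_blur(img, -1), "nonnegative")
})

test_that("scale family follows the adopted scale law", {
  set.seed(8)
  mg <- normalize_micrograph(matrix(runif(1e4), 100, 100))
  st <- build_scale_family(mg, scale_space_config(n_scales = 2))
  expect_equal(vapply(st$layers, function(l) nrow(l$image), 0L), c(71L, 100L))

  st16 <- build_scale_family(mg)
  expect_length(st16$layers, 16L)
  s <- vapply(st16$layers, `[[`, 0, "scale_factor")
  expect_true(all(diff(s) > 0))
  expect_equal(s[16], 1)
  for (l in st16$layers) {
    expect_gte(min(l$image), 0)
    expect_lte(max(l$image), 1)
  }
  # the coarsest factor is ~1/2, so only images below ~16 px can underflow
  tiny <- normalize_micrograph(matrix(runif(144), 12, 12))
  expect_error(build_scale_family(tiny), "too small")
})

test_that("DOG against the last octave image equals the brute-force subtraction", {
  set.seed(13)
  oct <- replicate(3, matrix(runif(64), 8, 8), simplify = FALSE)
  d <- dog_to_last(oct)
  expect_length(d, 2L)
  expect_identical(d[[1]], oct[[1]] - oct[[3]])
  expect_identical(d[[2]], oct[[2]] - oct[[3]])

  same <- replicate(4, oct[[1]], simplify = FALSE)
  expect_true(all(vapply(dog_to_last(same), function(x) all(x == 0), TRUE)))
  expect_error(dog_to_last(list(oct[[1]])), "two images")
  expect_error(dog_to_last(list(oct[[1]], matrix(0, 4, 4))), "shape")
})

test_that("feature matrix is nonnegative with lossless row roundtrip", {
  set.seed(34)
  diffs <- replicate(5, matrix(rnorm(64 * 64), 64, 64), simplify = FALSE)
  fm <- assemble_feature_matrix(diffs, c(64, 64))
  expect_equal(dim(fm$values), c(5L, 4096L))
  expect_identical(min(fm$values), 0)
  for (i in 1:5) {
    img <- feature_row_image(fm, i)
    expect_identical(as.vector(t(img)), fm$values[i, ])
    expect_equal(img, diffs[[i]] - fm$shift, tolerance = 1e-12)
  }
  expect_error(assemble_feature_matrix(list(), c(8, 8)), "no difference")
})

test_that("interframe analysis yields one row per DOG variation", {
  set.seed(2)
  mg <- normalize_micrograph(matrix(runif(96 * 80), 96, 80))
  cfg <- scale_space_config(n_scales = 4, scales_per_octave = 3)
  fm <- interframe_analysis(mg, cfg)
  expect_equal(nrow(fm$values), 4L * (3L - 1L))
  expect_equal(ncol(fm$values), 96L * 80L)
  expect_equal(nrow(fm$row_meta), nrow(fm$values))
  expect_true(all(fm$values >= 0))
})
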