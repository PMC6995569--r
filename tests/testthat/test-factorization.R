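test_that("exact low-rank inputs are recovered to numerical zero", {
  set.seed(42)
  for (xi in 1:2) {
    M <- Reduce(`+`, lapply(seq_len(xi), function(i) runif(12) %o% runif(40)))
    # multiplicative updates converge sublinearly near an exact optimum, so
    # the rank-2 case needs a generous iteration budget on this small input
    fp <- nnmf(M, nnmf_config(rank = xi, max_iter = 30000, tol = 1e-16, seed = 3))
    expect_lt(tail(fp$objective_trace, 1), 1e-8)
  }
})

test_that("objective trace is non-increasing for all three divergences", {
  set.seed(7)
  M <- matrix(runif(10 * 50, 0.05, 1), 10, 50)
  for (div in c("frobenius", "kullback_leibler", "itakura_saito")) {
    fp <- nnmf(M, nnmf_config(rank = 2, divergence = div, max_iter = 200,
                              tol = 1e-12, seed = 9))
    expect_true(all(diff(fp$objective_trace) <= 1e-9),
                label = paste("monotone trace for", div))
  }
})

test_that("negative input is rejected and rank is bounded", {
  M <- matrix(runif(50), 5, 10)
  M[2, 3] <- -0.1
  expect_error(nnmf(M), "negative")
  expect_error(nnmf(abs(M), nnmf_config(rank = 5)), "rank")
})

test_that("factorization is deterministic for a fixed seed", {
  set.seed(1)
  M <- matrix(runif(8 * 30), 8, 30)
  f1 <- nnmf(M, nnmf_config(seed = 77, max_iter = 50))
  f2 <- nnmf(M, nnmf_config(seed = 77, max_iter = 50))
  expect_identical(f1$S, f2$S)
  expect_identical(f1$H, f2$H)
  f3 <- nnmf(M, nnmf_config(seed = 78, max_iter = 50))
  expect_false(identical(f1$S, f3$S))
})

test_that("Itakura-Saito objective is invariant under global scaling", {
  set.seed(10)
  V <- matrix(runif(60, 0.1, 1), 6, 10)
  S <- matrix(runif(12, 0.1, 1), 6, 2)
  H <- matrix(runif(20, 0.1, 1), 2, 10)
  for (c in c(0.1, 3, 1000)) {
    expect_equal(nnmf_objective(c * V, c * S, H, "itakura_saito"),
                 nnmf_objective(V, S, H, "itakura_saito"), tolerance = 1e-8)
  }
})

test_that("channel reconstruction averages the rank-1 slices", {
  set.seed(5)
  V <- matrix(runif(6 * 48, 0.1, 1), 6, 48)
  fp <- nnmf(V, nnmf_config(rank = 2, max_iter = 100, seed = 2))
  ch <- reconstruct_channels(fp, c(6, 8))
  # candidate sum equals the row-averaged rank-2 reconstruction
  recon <- colMeans(fp$S %*% fp$H)
  expect_equal(as.vector(t(ch$candidate1 + ch$candidate2)), recon,
               tolerance = 1e-10)
  expect_true(all(ch$candidate1 >= 0) && all(ch$candidate2 >= 0))
  # permutation symmetry: swapping components swaps the candidates
  fp_sw <- fp
  fp_sw$S <- fp$S[, 2:1]; fp_sw$H <- fp$H[2:1, ]
  ch_sw <- reconstruct_channels(fp_sw, c(6, 8))
  expect_equal(ch_sw$candidate1, ch$candidate2)
  expect_equal(ch_sw$candidate2, ch$candidate1)
  # rank-1 pair is rejected
  fp1 <- nnmf(V, nnmf_config(rank = 1, max_iter = 20, seed = 2))
  expect_error(reconstruct_channels(fp1, c(6, 8)), "rank-2")
})

test_that("channel assignment puts the high-frequency candidate in W1", {
  m <- 64
  sharp <- matrix(0, m, m)
  for (ctr in list(c(16, 16), c(48, 40), c(30, 55)))
    sharp[disk_mask(m, m, ctr[1], ctr[2], 4)] <- 1
  smooth <- outer(seq(0, 1, length.out = m), seq(0, 1, length.out = m), `+`) / 2
  ch <- assign_channels(sharp, smooth)
  expect_identical(ch$W1, sharp)
  expect_identical(ch$structure_index, 1L)
  expect_gt(ch$assignment_score, 1)
  # order invariance of contents
  ch2 <- assign_channels(smooth, sharp)
  expect_identical(ch2$W1, sharp)
  expect_identical(ch2$W2, smooth)
  # exact tie goes to the first component
  tie <- assign_channels(sharp, sharp)
  expect_identical(tie$structure_index, 1L)
})
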