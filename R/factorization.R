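#' NNMF configuration
#'
#' @param rank factorization rank (xi); the pipeline uses 2 (structure +
#'   background).
#' @param divergence objective: `"frobenius"`, `"kullback_leibler"` or
#'   `"itakura_saito"`. Multiplicative updates for each.
#' @param max_iter iteration cap.
#' @param tol stop when the relative objective change falls below this.
#' @param seed integer seed for the random initialization.
#' @return An `NNMFConfig` list.
#' @export
nnmf_config <- function(rank = 2L,
                        divergence = c("frobenius", "kullback_leibler",
                                       "itakura_saito"),
                        max_iter = 500L, tol = 1e-5, seed = 1L) {
  divergence <- match.arg(divergence)
  if (rank < 1L) stop("rank must be positive", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be positive", call. = FALSE)
  structure(list(rank = as.integer(rank), divergence = divergence,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "NNMFConfig")
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Approximates a nonnegative matrix `V` (R x N) as `S %*% H` with
#' `S >= 0` (R x rank) and `H >= 0` (rank x N), minimizing the chosen
#' divergence. Initialization is seeded uniform random in (0, 1], so the
#' result is reproducible for a fixed config. The objective trace is
#' non-increasing (a property of the multiplicative updates for all three
#' divergences).
#'
#' For the Frobenius objective the updates are evaluated through the
#' Gram matrices `t(S) %*% S` and `H %*% t(H)`, so the R x N product
#' `S %*% H` is never formed; this keeps the memory footprint small for
#' wide feature matrices. KL and Itakura-Saito form the reconstruction
#' explicitly and a floor of 1e-12 is added to `V` to keep the ratios
#' finite.
#'
#' @param V nonnegative numeric matrix or a `FeatureMatrix`.
#' @param config an [nnmf_config()].
#' @return A `FactorPair`: list with `S`, `H`, `objective_trace`,
#'   `n_iter`, `converged`, `divergence`.
#' @export
nnmf <- function(V, config = nnmf_config()) {
  if (inherits(V, "FeatureMatrix")) V <- V$values
  if (!is.matrix(V)) stop("V must be a matrix", call. = FALSE)
  if (min(V) < 0)
    stop("V has negative entries; NNMF requires nonnegative input", call. = FALSE)
  R <- nrow(V); N <- ncol(V); xi <- config$rank
  if (xi >= min(R, N))
    stop("rank must be smaller than both matrix dimensions", call. = FALSE)
  eps <- 1e-12
  div <- config$divergence
  withr::with_seed(config$seed, {
    S <- matrix(runif(R * xi, min = eps, max = 1), R, xi)
    H <- matrix(runif(xi * N, min = eps, max = 1), xi, N)
  })
  if (div != "frobenius") V <- V + eps
  obj <- function(S, H) nnmf_objective(V, S, H, div)
  trace <- numeric(config$max_iter + 1L)
  n_done <- 0L
  converged <- FALSE
  if (div == "frobenius") {
    # the two R x N products per iteration dominate; sum(V^2) is hoisted
    # and S'V shared between the H update and the objective
    normV2 <- sum(V * V)
    StV <- crossprod(S, V)
    trace[1L] <- 0.5 * (normV2 - 2 * sum(StV * H) +
                        sum(crossprod(S) * tcrossprod(H)))
    for (it in seq_len(config$max_iter)) {
      H <- H * StV / pmax(crossprod(S) %*% H, eps)
      S <- S * tcrossprod(V, H) / pmax(S %*% tcrossprod(H), eps)
      n_done <- it
      StV <- crossprod(S, V)
      trace[it + 1L] <- 0.5 * (normV2 - 2 * sum(StV * H) +
                               sum(crossprod(S) * tcrossprod(H)))
      prev <- trace[it]
      if (prev > 0 && abs(prev - trace[it + 1L]) / prev < config$tol) {
        converged <- TRUE
        break
      }
    }
    return(structure(list(S = S, H = H,
                          objective_trace = trace[seq_len(n_done + 1L)],
                          n_iter = n_done, converged = converged,
                          divergence = div),
                     class = "FactorPair"))
  }
  trace[1L] <- obj(S, H)
  for (it in seq_len(config$max_iter)) {
    if (div == "kullback_leibler") {
      Vh <- pmax(S %*% H, eps)
      H <- H * crossprod(S, V / Vh) / pmax(colSums(S), eps)
      Vh <- pmax(S %*% H, eps)
      S <- S * tcrossprod(V / Vh, H) %*% diag(1 / pmax(rowSums(H), eps), xi)
    } else { # itakura_saito
      Vh <- pmax(S %*% H, eps)
      H <- H * crossprod(S, V / Vh^2) / pmax(crossprod(S, 1 / Vh), eps)
      Vh <- pmax(S %*% H, eps)
      S <- S * tcrossprod(V / Vh^2, H) / pmax(tcrossprod(1 / Vh, H), eps)
    }
    n_done <- it
    trace[it + 1L] <- obj(S, H)
    prev <- trace[it]
    if (prev > 0 && abs(prev - trace[it + 1L]) / prev < config$tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(S = S, H = H,
                 objective_trace = trace[seq_len(n_done + 1L)],
                 n_iter = n_done, converged = converged, divergence = div),
            class = "FactorPair")
}

#' @export
print.FactorPair <- function(x, ...) {
  cat(sprintf("FactorPair: %d x %d ~ (%d x %d)(%d x %d), %s, %d iters%s\n",
              nrow(x$S), ncol(x$H), nrow(x$S), ncol(x$S), nrow(x$H), ncol(x$H),
              x$divergence, x$n_iter, if (x$converged) " (converged)" else ""))
  cat(sprintf("  final objective %.6g\n", tail(x$objective_trace, 1)))
  invisible(x)
}

#' NNMF objective value
#'
#' Evaluates the divergence between `V` and `S %*% H`. Frobenius is
#' `0.5 ||V - SH||_F^2` (computed through Gram matrices, without forming
#' `SH`); Kullback-Leibler and Itakura-Saito are the usual elementwise
#' sums with a 1e-12 floor on the reconstruction. The Itakura-Saito
#' divergence is scale-invariant: scaling `V` and `SH` by the same
#' positive constant leaves it unchanged.
#'
#' @param V nonnegative matrix.
#' @param S,H factor matrices.
#' @param divergence objective name as in [nnmf_config()].
#' @return Scalar objective value.
#' @export
nnmf_objective <- function(V, S, H,
                           divergence = c("frobenius", "kullback_leibler",
                                          "itakura_saito")) {
  divergence <- match.arg(divergence)
  eps <- 1e-12
  if (divergence == "frobenius") {
    StS <- crossprod(S)           # xi x xi
    HHt <- tcrossprod(H)          # xi x xi
    cross <- sum(crossprod(S, V) * H)
    0.5 * (sum(V * V) - 2 * cross + sum(StS * HHt))
  } else {
    Vh <- pmax(S %*% H, eps)
    if (divergence == "kullback_leibler") sum(V * log(V / Vh) - V + Vh)
    else sum(V / Vh - log(V / Vh) - 1)
  }
}

#' Reconstruct the two channel images from a rank-2 factor pair
#'
#' For each component j the rank-1 slice `S[, j] %o% H[j, ]` spans all R
#' scale rows; it is collapsed by averaging over the rows (equivalently,
#' `mean(S[, j]) * H[j, ]`) and reshaped to the origin shape, yielding two
#' nonnegative candidate channel images whose sum equals the row-averaged
#' rank-2 reconstruction.
#'
#' @param fp a `FactorPair` with rank 2.
#' @param origin_shape integer `c(m, n)`.
#' @return List with `candidate1`, `candidate2` (m x n matrices).
#' @export
reconstruct_channels <- function(fp, origin_shape) {
  if (ncol(fp$S) != 2L)
    stop("channel reconstruction requires a rank-2 factorization", call. = FALSE)
  chan <- lapply(1:2, function(j)
    feature_row_image(mean(fp$S[, j]) * fp$H[j, ], shape = origin_shape))
  list(candidate1 = chan[[1]], candidate2 = chan[[2]])
}

#' Assign structure (W1) and background (W2) channels
#'
#' The factorization is symmetric in its two components, so an assignment
#' rule is needed. Particles carry the high-spatial-frequency content:
#' the candidate with the larger normalized high-pass energy (spectral
#' power above the radial median frequency of the grid) becomes the
#' structure channel W1; ties go to the first component.
#'
#' @param candidate1,candidate2 same-shape nonnegative matrices.
#' @return A `ChannelPair`: list with `W1`, `W2`, `assignment_score`
#'   (ratio of the two high-pass energies) and `structure_index`.
#' @export
assign_channels <- function(candidate1, candidate2) {
  if (!all(dim(candidate1) == dim(candidate2)))
    stop("candidates must share one shape", call. = FALSE)
  e1 <- highpass_energy_fraction(candidate1)
  e2 <- highpass_energy_fraction(candidate2)
  idx <- if (e2 > e1) 2L else 1L  # tie -> component 1
  structure(list(W1 = if (idx == 1L) candidate1 else candidate2,
                 W2 = if (idx == 1L) candidate2 else candidate1,
                 assignment_score = if (idx == 1L) e1 / max(e2, 1e-300)
                                    else e2 / max(e1, 1e-300),
                 structure_index = idx),
            class = "ChannelPair")
}

# Fraction of non-DC spectral power above the radial median frequency of
# the frequency grid.
highpass_energy_fraction <- function(img) {
  m <- nrow(img); n <- ncol(img)
  P <- Mod(fft(img - mean(img)))^2
  fr <- fft_freq(m); fc <- fft_freq(n)
  f <- sqrt(outer(fr^2, fc^2, "+"))
  fmed <- median(f[f > 0])
  tot <- sum(P[f > 0])
  if (tot == 0) return(0)
  sum(P[f > fmed]) / tot
}

# normalized DFT frequencies |f| in cycles/px for an axis of length n
fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  pmin(k, n - k) / n
}
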