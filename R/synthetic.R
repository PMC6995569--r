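#' Simulation configuration for synthetic KLH-like micrographs
#'
#' The simulator emulates the salient statistics of real low-dose
#' micrographs of a large barrel-shaped macromolecule: a 1/f^beta
#' (pink-noise) background, dark particles on a brighter background, two
#' view classes (annular top views and striated rectangular side views),
#' and a low signal-to-noise ratio.
#'
#' @param shape image dimensions `c(m, n)` (default 512 x 512).
#' @param n_top,n_side particle counts per view class.
#' @param top_outer_radius,top_inner_radius annulus radii in px
#'   (defaults 18 and 10).
#' @param side_length,side_width rectangle dimensions in px (defaults
#'   56 x 16).
#' @param snr_db signal-to-noise ratio in dB, `10*log10(P_signal /
#'   P_noise)` with signal power measured over the particle footprint
#'   (default 10, the upper end of the low-SNR regime).
#' @param noise_beta spectral exponent of the 1/f^beta background
#'   (default 1, pink noise).
#' @param min_separation minimum centre-to-centre distance between
#'   particles in px (default 45).
#' @param seed integer seed; identical configs give bit-identical output.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(shape = c(512L, 512L), n_top = 6L, n_side = 6L,
                       top_outer_radius = 18, top_inner_radius = 10,
                       side_length = 56, side_width = 16,
                       snr_db = 10, noise_beta = 1, min_separation = 45,
                       seed = 1L) {
  if (min_separation <= 0) stop("min_separation must be positive", call. = FALSE)
  if (top_inner_radius >= top_outer_radius)
    stop("top_inner_radius must be < top_outer_radius", call. = FALSE)
  if (noise_beta < 0) stop("noise_beta must be >= 0", call. = FALSE)
  structure(list(shape = as.integer(shape), n_top = as.integer(n_top),
                 n_side = as.integer(n_side),
                 top_outer_radius = top_outer_radius,
                 top_inner_radius = top_inner_radius,
                 side_length = side_length, side_width = side_width,
                 snr_db = snr_db, noise_beta = noise_beta,
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "SimConfig")
}

#' 1/f^beta spatial noise field
#'
#' Shapes the spectrum of a white Gaussian field with an amplitude filter
#' proportional to `1/f^(beta/2)` (power `1/f^beta`), zeroes the DC term,
#' and standardizes the result to zero mean and unit variance. `beta = 0`
#' reduces to white noise; `beta = 1` is the pink-noise statistic of real
#' micrograph backgrounds.
#'
#' @param shape `c(m, n)`.
#' @param beta spectral exponent, >= 0.
#' @param seed integer seed.
#' @return m x n numeric matrix.
#' @export
pink_noise <- function(shape, beta = 1, seed = 1L) {
  m <- shape[1]; n <- shape[2]
  w <- withr::with_seed(as.integer(seed), matrix(rnorm(m * n), m, n))
  if (beta == 0) {
    z <- w
  } else {
    f <- sqrt(outer(fft_freq(m)^2, fft_freq(n)^2, "+"))
    amp <- ifelse(f > 0, f^(-beta / 2), 0)  # DC removed
    z <- Re(fft(fft(w) * amp, inverse = TRUE)) / (m * n)
  }
  (z - mean(z)) / sd(z)
}

# footprint stamps: list(rows, cols (0-based), intensity in [0,1] depth units)
stamp_top <- function(outer_r, inner_r) {
  h <- ceiling(outer_r)
  g <- expand.grid(r = -h:h, c = -h:h)
  rad <- sqrt(g$r^2 + g$c^2)
  sel <- rad <= outer_r & rad >= inner_r
  list(rows = g$r[sel], cols = g$c[sel], depth = rep(1, sum(sel)))
}

stamp_side <- function(len, wid, phi) {
  h <- ceiling(sqrt(len^2 + wid^2) / 2)
  g <- expand.grid(r = -h:h, c = -h:h)
  u <- g$c * cos(phi) + g$r * sin(phi)    # along the long axis
  v <- -g$c * sin(phi) + g$r * cos(phi)
  sel <- abs(u) <= len / 2 & abs(v) <= wid / 2
  vv <- v[sel]
  # two lighter internal striations running along the length
  striae <- abs(abs(vv) - wid / 4) < wid / 10
  depth <- ifelse(striae, 0.45, 1)
  list(rows = g$r[sel], cols = g$c[sel], depth = depth)
}

#' Simulate a micrograph with known ground truth
#'
#' Draws `n_top` annular and `n_side` rectangular particles as dark shapes
#' on a brighter background (cryo-EM contrast), places them by rejection
#' sampling under the minimum-separation constraint, adds 1/f^beta noise
#' scaled so the footprint signal-to-noise ratio matches `snr_db`, and
#' returns the micrograph together with the ground-truth records.
#'
#' @param config a [sim_config()].
#' @return List with `micrograph` (a [micrograph()]) and `truth` (a
#'   data.frame with columns `row`, `col`, `view`, `orientation`, `dim1`,
#'   `dim2`), plus `achieved_snr_db`.
#' @export
simulate_micrograph <- function(config = sim_config()) {
  m <- config$shape[1]; n <- config$shape[2]
  margin <- 2 * config$top_outer_radius
  n_part <- config$n_top + config$n_side
  withr::with_seed(config$seed, {
    centers <- matrix(NA_real_, 0L, 2L)
    attempts <- 0L
    while (nrow(centers) < n_part) {
      if (attempts >= 1000L)
        stop(sprintf("placement failed: %d of %d particles placed after 1000 attempts",
                     nrow(centers), n_part), call. = FALSE)
      cand <- c(runif(1, margin, m - 1 - margin), runif(1, margin, n - 1 - margin))
      attempts <- attempts + 1L
      if (nrow(centers) == 0L ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= config$min_separation)
        centers <- rbind(centers, cand)
    }
    orientations <- runif(n_part, 0, pi)
  })
  views <- rep(c("top", "side"), c(config$n_top, config$n_side))
  signal <- matrix(0, m, n)
  truth <- vector("list", n_part)
  for (k in seq_len(n_part)) {
    ctr <- round(centers[k, ])
    if (views[k] == "top") {
      st <- stamp_top(config$top_outer_radius, config$top_inner_radius)
      ori <- 0
      dims <- c(config$top_outer_radius, config$top_inner_radius)
    } else {
      ori <- orientations[k]
      st <- stamp_side(config$side_length, config$side_width, ori)
      dims <- c(config$side_length, config$side_width)
    }
    rr <- ctr[1] + st$rows + 1L; cc <- ctr[2] + st$cols + 1L
    inb <- rr >= 1L & rr <= m & cc >= 1L & cc <= n
    signal[cbind(rr[inb], cc[inb])] <- -st$depth[inb]  # dark particles
    truth[[k]] <- data.frame(row = ctr[1], col = ctr[2], view = views[k],
                             orientation = ori, dim1 = dims[1], dim2 = dims[2])
  }
  truth <- if (n_part > 0L) do.call(rbind, truth) else
    data.frame(row = numeric(), col = numeric(), view = character(),
               orientation = numeric(), dim1 = numeric(), dim2 = numeric())
  noise <- pink_noise(c(m, n), config$noise_beta, seed = config$seed + 104729L)
  footprint <- signal != 0
  if (any(footprint)) {
    p_sig <- mean(signal[footprint]^2)
    alpha <- sqrt(p_sig / 10^(config$snr_db / 10))  # noise sd: unit-var noise scaled
  } else {
    alpha <- 1
  }
  pixels <- 0.5 + signal + alpha * noise
  achieved <- if (any(footprint)) 10 * log10(p_sig / alpha^2) else NA_real_
  list(micrograph = micrograph(pixels), truth = truth,
       achieved_snr_db = achieved)
}
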