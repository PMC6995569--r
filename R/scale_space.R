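#' Scale-space configuration
#'
#' Parameters of the multi-scale interframe analysis: the number of
#' rescaled layers, the Perona-Malik diffusion settings and the Gaussian
#' octave structure.
#'
#' @param n_scales number of rescaled layers U (default 16).
#' @param pm_K Perona-Malik contrast constant K (default 0.05, for images
#'   normalized to `[0, 1]`): gradients well above K are treated as borders
#'   and diffuse slowly.
#' @param pm_iters_per_scale base iteration count; layer u runs
#'   `pm_iters_per_scale * u` explicit diffusion steps so coarser layers are
#'   smoothed more.
#' @param pm_dt explicit time step, must lie in (0, 0.25] for stability of
#'   the 4-neighbour scheme.
#' @param sigma_base base Gaussian standard deviation (px) for the
#'   within-octave blur sequence.
#' @param scales_per_octave number of Gaussian images per octave; sigma is
#'   multiplied by `2^(1/scales_per_octave)` between consecutive images.
#' @return A `ScaleSpaceConfig` list.
#' @export
scale_space_config <- function(n_scales = 16L, pm_K = 0.05,
                               pm_iters_per_scale = 5L, pm_dt = 0.2,
                               sigma_base = 1.6, scales_per_octave = 4L) {
  if (n_scales < 2L) stop("n_scales must be >= 2", call. = FALSE)
  if (pm_K <= 0) stop("pm_K must be positive", call. = FALSE)
  if (pm_dt <= 0 || pm_dt > 0.25)
    stop("pm_dt must lie in (0, 0.25] for stability", call. = FALSE)
  if (pm_iters_per_scale < 1L) stop("pm_iters_per_scale must be >= 1", call. = FALSE)
  if (sigma_base <= 0) stop("sigma_base must be positive", call. = FALSE)
  if (scales_per_octave < 2L)
    stop("scales_per_octave must be >= 2 (an octave needs >= 2 images for DOG)",
         call. = FALSE)
  structure(list(n_scales = as.integer(n_scales), pm_K = pm_K,
                 pm_iters_per_scale = as.integer(pm_iters_per_scale),
                 pm_dt = pm_dt, sigma_base = sigma_base,
                 scales_per_octave = as.integer(scales_per_octave)),
            class = "ScaleSpaceConfig")
}

#' Perona-Malik anisotropic diffusion
#'
#' Explicit 4-neighbour finite-difference scheme with reflecting (Neumann)
#' boundaries and diffusivity `g(s) = exp(-(s/K)^2)`, decreasing in the
#' gradient magnitude s: smoothing is strong in uniform areas and weak
#' across borders. Total intensity is conserved and the intensity range
#' does not expand.
#'
#' @param image numeric matrix, intensities in `[0, 1]`.
#' @param K contrast constant, > 0.
#' @param n_iter number of explicit steps.
#' @param dt time step in (0, 0.25].
#' @return Diffused matrix of the same shape.
#' @examples
#' x <- matrix(runif(25), 5, 5)
#' y <- pm_diffuse(x, K = 0.05, n_iter = 3)
#' abs(sum(y) - sum(x)) < 1e-9 * sum(x)
#' @export
pm_diffuse <- function(image, K = 0.05, n_iter = 5L, dt = 0.2) {
  if (dt <= 0 || dt > 0.25)
    stop("dt must lie in (0, 0.25] for stability", call. = FALSE)
  if (K <= 0) stop("K must be positive", call. = FALSE)
  if (n_iter < 0) stop("n_iter must be nonnegative", call. = FALSE)
  if (n_iter == 0L) return(image)
  pm_diffuse_cpp(image, K, as.integer(n_iter), dt)
}

#' Gaussian blur with a truncated, renormalized kernel
#'
#' Isotropic Gaussian smoothing `g_ij = exp(-(i^2+j^2)/(2 sigma^2)) /
#' (2 pi sigma^2)`, truncated at +/- 4 sigma and renormalized to unit sum,
#' applied separably with reflecting boundaries. Unit kernel sum plus
#' reflection makes the operator mean-preserving. `sigma = 0` is the
#' identity.
#'
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels, >= 0.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  if (sigma == 0) return(image)
  k <- gaussian_kernel_1d(sigma)
  # the truncated 2D kernel is the outer product of the renormalized 1D taps
  t(conv_reflect_1d(t(conv_reflect_1d(image, k)), k))
}

# 1D Gaussian taps at integer offsets -ceil(4 sigma)..ceil(4 sigma),
# renormalized to unit sum. The 2D kernel of the model is the outer
# product of this vector with itself.
gaussian_kernel_1d <- function(sigma) {
  h <- ceiling(4 * sigma)
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Column-direction convolution with reflect padding, vectorized as a sum
# of row-shifted copies. `k` of odd length; empty k = identity.
conv_reflect_1d <- function(image, k) {
  if (length(k) == 0L) return(image)
  m <- nrow(image)
  h <- (length(k) - 1L) %/% 2L
  # half-sample symmetric padding: ...,x2,x1 | x1..xm | xm,xm-1,...
  if (h <= m) {
    idx <- c(rev(seq_len(h)), seq_len(m), m + 1L - seq_len(h))
  } else { # very wide kernel on a tiny image: fold repeatedly
    idx <- reflect_index(seq(1L - h, m + h), m)
  }
  pad <- image[idx, , drop = FALSE]
  out <- matrix(0, m, ncol(image))
  for (t in seq_along(k))
    out <- out + k[t] * pad[(t - 1L) + seq_len(m), , drop = FALSE]
  out
}

reflect_index <- function(i, m) {
  # map arbitrary integer index onto 1..m by mirror reflection
  p <- (i - 1L) %% (2L * m)
  ifelse(p < m, p + 1L, 2L * m - p)
}

#' Build the Perona-Malik scale family
#'
#' Constructs U rescaled layers of a normalized micrograph. Layer u
#' (u = 1..U) is the input bilinearly resampled by the factor
#' `s_u = 2^(u/U - 1)` (resampled pixel dimensions rounded to the nearest
#' integer; the last layer is full size) and then Perona-Malik diffused
#' with `pm_iters_per_scale * u` iterations, so smoothing increases with
#' the layer index.
#'
#' @param mg normalized [micrograph()] (or matrix in `[0, 1]`).
#' @param config a [scale_space_config()].
#' @return A `ScaleStack`: list with `layers` (each a list with
#'   `scale_index`, `scale_factor`, `image`) and `origin_shape`.
#' @export
build_scale_family <- function(mg, config = scale_space_config()) {
  px <- as_pixels(mg)
  if (min(px) < 0 || max(px) > 1)
    stop("micrograph must be normalized to [0, 1] first", call. = FALSE)
  U <- config$n_scales
  m <- nrow(px); n <- ncol(px)
  layers <- vector("list", U)
  for (u in seq_len(U)) {
    s_u <- 2^(u / U - 1)
    mu <- as.integer(round(m * s_u)); nu <- as.integer(round(n * s_u))
    if (mu < 8L || nu < 8L)
      stop(sprintf("layer %d would be %dx%d: input too small for n_scales=%d",
                   u, mu, nu, U), call. = FALSE)
    img <- if (mu == m && nu == n) px else resample_bilinear_cpp(px, mu, nu)
    img <- pm_diffuse(img, K = config$pm_K,
                      n_iter = config$pm_iters_per_scale * u,
                      dt = config$pm_dt)
    layers[[u]] <- list(scale_index = u, scale_factor = s_u, image = img)
  }
  structure(list(layers = layers, origin_shape = c(m, n)),
            class = "ScaleStack")
}

#' @export
print.ScaleStack <- function(x, ...) {
  cat(sprintf("ScaleStack: %d layers, origin %d x %d\n",
              length(x$layers), x$origin_shape[1], x$origin_shape[2]))
  invisible(x)
}

#' Difference-of-Gaussians within one octave, against the last image
#'
#' Given the ordered Gaussian blur sequence of one octave, returns the
#' element-wise differences of every image against the last (most blurred)
#' one. Differences may be negative; [assemble_feature_matrix()] shifts
#' them later.
#'
#' @param octave_layers list of >= 2 equally sized numeric matrices.
#' @return List of `length(octave_layers) - 1` difference matrices.
#' @export
dog_to_last <- function(octave_layers) {
  if (!is.list(octave_layers) || length(octave_layers) < 2L)
    stop("need at least two images in an octave", call. = FALSE)
  dims <- vapply(octave_layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("octave images must share one shape", call. = FALSE)
  last <- octave_layers[[length(octave_layers)]]
  lapply(octave_layers[-length(octave_layers)], function(im) im - last)
}

#' Assemble the scale-space feature matrix
#'
#' Resamples each difference image back to the origin shape, flattens it
#' row-major into one row, and shifts the whole matrix by its global
#' minimum so all entries are nonnegative (a requirement of the NNMF
#' stage). Subtracting the minimum, rather than clipping, preserves the
#' relative structure of the DOG responses.
#'
#' @param difference_images list of numeric matrices (any sizes).
#' @param origin_shape integer vector `c(m, n)`.
#' @param row_meta optional data.frame with one row of provenance per
#'   difference image (scale index, octave position, sigma).
#' @return A `FeatureMatrix`: list with `values` (R x m*n nonnegative
#'   matrix), `row_meta`, `origin_shape` and `shift` (the subtracted
#'   minimum).
#' @export
assemble_feature_matrix <- function(difference_images, origin_shape,
                                    row_meta = NULL) {
  if (length(difference_images) == 0L)
    stop("no difference images supplied", call. = FALSE)
  m <- origin_shape[1]; n <- origin_shape[2]
  R <- length(difference_images)
  values <- matrix(0, R, m * n)
  for (i in seq_len(R)) {
    im <- difference_images[[i]]
    if (nrow(im) != m || ncol(im) != n)
      im <- resample_bilinear_cpp(im, m, n)
    values[i, ] <- as.vector(t(im)) # row-major flatten
  }
  shift <- min(values)
  values <- values - shift
  if (is.null(row_meta))
    row_meta <- data.frame(scale_index = seq_len(R), octave_index = NA_integer_,
                           sigma = NA_real_)
  structure(list(values = values, row_meta = row_meta,
                 origin_shape = c(m, n), shift = shift),
            class = "FeatureMatrix")
}

#' Reshape one feature-matrix row back to image form
#'
#' Inverse of the row-major flattening used by [assemble_feature_matrix()].
#'
#' @param fm a `FeatureMatrix` (or a plain numeric vector plus `shape`).
#' @param i row index.
#' @param shape origin shape, taken from `fm` when omitted.
#' @return m x n numeric matrix.
#' @export
feature_row_image <- function(fm, i, shape = NULL) {
  if (inherits(fm, "FeatureMatrix")) {
    v <- fm$values[i, ]
    shape <- fm$origin_shape
  } else v <- fm
  matrix(v, nrow = shape[1], ncol = shape[2], byrow = TRUE)
}

#' Full Phase-I interframe analysis
#'
#' Runs the scale family, per-layer Gaussian octaves and DOG stacking, and
#' assembles the feature matrix. Each of the U layers forms one octave:
#' the diffused layer is blurred at
#' `sigma_base * 2^((j-1)/scales_per_octave)`, j = 1..scales_per_octave,
#' and each blurred image is differenced against the last of its octave,
#' giving `U * (scales_per_octave - 1)` feature rows.
#'
#' @inheritParams build_scale_family
#' @return A `FeatureMatrix`.
#' @export
interframe_analysis <- function(mg, config = scale_space_config()) {
  stack <- build_scale_family(mg, config)
  spo <- config$scales_per_octave
  sigmas <- config$sigma_base * 2^((seq_len(spo) - 1) / spo)
  diffs <- list(); meta <- list()
  for (layer in stack$layers) {
    octave <- lapply(sigmas, function(s) gaussian_blur(layer$image, s))
    d <- dog_to_last(octave)
    for (j in seq_along(d)) {
      diffs[[length(diffs) + 1L]] <- d[[j]]
      meta[[length(meta) + 1L]] <- data.frame(
        scale_index = layer$scale_index, octave_index = j, sigma = sigmas[j])
    }
  }
  assemble_feature_matrix(diffs, stack$origin_shape, do.call(rbind, meta))
}
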