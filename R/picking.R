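#' Picking configuration
#'
#' @param area_min,area_max inclusive connected-component area gate in
#'   pixels (defaults 100 and 1500, matching the expected macromolecule
#'   footprint at the working magnification).
#' @param radius ray length r in pixels for radial profiling (<= 50).
#' @param n_rays number of equally spaced ray angles.
#' @param connectivity 4 or 8 for component labeling.
#' @param cepstrum_accept_threshold acceptance threshold on the cepstrum
#'   coherence score.
#' @return A `PickingConfig` list.
#' @export
picking_config <- function(area_min = 100L, area_max = 1500L, radius = 50L,
                           n_rays = 64L, connectivity = 8L,
                           cepstrum_accept_threshold = 0.15) {
  if (area_min >= area_max) stop("area_min must be < area_max", call. = FALSE)
  if (radius < 1L || radius > 50L)
    stop("radius must lie in [1, 50] px", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  if (n_rays < 4L) stop("n_rays must be >= 4", call. = FALSE)
  structure(list(area_min = as.integer(area_min),
                 area_max = as.integer(area_max),
                 radius = as.integer(radius), n_rays = as.integer(n_rays),
                 connectivity = as.integer(connectivity),
                 cepstrum_accept_threshold = cepstrum_accept_threshold),
            class = "PickingConfig")
}

#' Otsu threshold over 256 uniform bins
#'
#' Exhaustively maximizes the between-class variance over the 255 cut
#' points of a 256-bin histogram on `[0, 1]`. The binary image is
#' `image >= threshold`. A constant image is degenerate: the threshold is
#' that constant, the foreground empty, and `degenerate` is set.
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @return List with `threshold`, `binary` (logical matrix), `degenerate`.
#' @export
otsu_threshold <- function(image) {
  v <- as.vector(image)
  if (min(v) < 0 || max(v) > 1)
    stop("image must lie in [0, 1]", call. = FALSE)
  if (max(v) == min(v)) {
    return(list(threshold = v[1],
                binary = matrix(FALSE, nrow(image), ncol(image)),
                degenerate = TRUE))
  }
  nb <- 256L
  bins <- pmin(floor(v * nb), nb - 1L)          # bin index 0..255
  h <- tabulate(bins + 1L, nbins = nb)
  p <- h / sum(h)
  centers <- (seq_len(nb) - 0.5) / nb
  w0 <- cumsum(p)                               # P(class 0) for cut after bin c
  mu <- cumsum(p * centers)
  mu_T <- mu[nb]
  cuts <- seq_len(nb - 1L)                      # cut between bin c-1 and c
  w0c <- w0[cuts]; mu0 <- mu[cuts]
  valid <- w0c > 0 & w0c < 1
  sigma_b <- rep(-Inf, nb - 1L)
  sigma_b[valid] <- (mu_T * w0c[valid] - mu0[valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  cbest <- which.max(sigma_b)                   # first maximizer
  thr <- cbest / nb                             # lower edge of first fg bin
  list(threshold = thr, binary = image >= thr, degenerate = FALSE)
}

#' Label connected components
#'
#' Breadth-first flood-fill labeling with selectable 4- or 8-connectivity;
#' labels follow raster order of each component's first pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  storage.mode(mask) <- "logical"
  label_components_cpp(mask, as.integer(connectivity))
}

#' Extract size-gated region candidates
#'
#' Labels the connected components of the background-channel binary `B2`
#' (whose blobs have well-delineated centroids), keeps those with area
#' inside the inclusive `[area_min, area_max]` gate, and for each computes
#' its centroid, radial border profiles against the structure binary `B1`,
#' the polar-unwrapped intensity patch from `W2`, and the cepstrum score.
#' Candidates are ordered by centroid (row, then col), which makes
#' end-to-end runs reproducible.
#'
#' @param B1 logical matrix, binarized structure channel (border source).
#' @param B2 logical matrix, binarized background/blob channel
#'   (centroid source).
#' @param W2 numeric matrix, the channel sampled for polar patches.
#' @param config a [picking_config()].
#' @return List of `RegionCandidate` objects, each a list with `label`,
#'   `centroid`, `area`, `bbox` (half-open, 0-based), `profiles`,
#'   `border_distances`, `polar_patch`, `cepstrum_score`, `accepted`.
#' @export
extract_candidates <- function(B1, B2, W2, config = picking_config()) {
  stopifnot(all(dim(B1) == dim(B2)), all(dim(B2) == dim(W2)))
  lab <- label_components(B2, config$connectivity)
  nlab <- max(lab)
  if (nlab == 0L) {
    out <- list()
    attr(out, "label_matrix") <- lab
    return(out)
  }
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which(areas >= config$area_min & areas <= config$area_max)
  cands <- lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    centroid <- c(mean(idx[, 1]), mean(idx[, 2])) - 1  # 0-based
    bbox <- c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
              max(idx[, 1]), max(idx[, 2]))            # half-open, 0-based
    rp <- radial_profiles(B1, centroid, config)
    gp <- polar_unwrap(W2, centroid, config)
    cs <- cepstrum_accept(gp, config)
    list(label = k, centroid = centroid, area = areas[k], bbox = bbox,
         profiles = rp$profiles, border_distances = rp$border_distances,
         polar_patch = gp, cepstrum_score = cs$score, accepted = cs$accepted)
  })
  ord <- order(vapply(cands, function(c) c$centroid[1], 0),
               vapply(cands, function(c) c$centroid[2], 0))
  out <- cands[ord]
  attr(out, "label_matrix") <- lab
  out
}

# ray sampling grid: integer steps 1..r at n_rays uniform angles;
# returns row/col index matrices (1-based, NA when out of bounds)
ray_indices <- function(centroid, shape, n_rays, r) {
  theta <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays
  rho <- seq_len(r)
  rows <- round(outer(sin(theta), rho) + centroid[1]) + 1L  # 1-based
  cols <- round(outer(cos(theta), rho) + centroid[2]) + 1L
  bad <- rows < 1L | rows > shape[1] | cols < 1L | cols > shape[2]
  rows[bad] <- NA_integer_; cols[bad] <- NA_integer_
  list(rows = rows, cols = cols)
}

#' Radial profiles and border distances
#'
#' Traces `n_rays` concentric rays of length `radius` from the centroid at
#' uniformly spaced angles, sampling the binary image by nearest pixel
#' (out-of-bounds reads as 0). The border distance of ray i is the step
#' index of the first positive impulse of the discrete derivative of its
#' profile, or 0 when no impulse exists.
#'
#' @param B logical (or 0/1 numeric) matrix.
#' @param centroid numeric `(row, col)`, 0-based.
#' @param config a [picking_config()].
#' @return List with `profiles` (n_rays x radius 0/1 matrix) and
#'   `border_distances` (integer vector of length n_rays).
#' @export
radial_profiles <- function(B, centroid, config = picking_config()) {
  ri <- ray_indices(centroid, dim(B), config$n_rays, config$radius)
  vals <- B[cbind(as.vector(ri$rows), as.vector(ri$cols))]
  prof <- matrix(as.numeric(vals), config$n_rays, config$radius)
  prof[is.na(prof)] <- 0
  d <- apply(prof, 1L, function(p) {
    imp <- which(diff(p) > 0)
    if (length(imp) == 0L) 0L else imp[1L] + 1L
  })
  list(profiles = prof, border_distances = as.integer(d))
}

#' Polar unwrap of a channel around a centroid
#'
#' Samples the intensity channel along the same ray grid as
#' [radial_profiles()]; row i of the result is the intensity profile along
#' ray i, so a closed border appears as a vertical band.
#'
#' @param W numeric matrix.
#' @inheritParams radial_profiles
#' @return `n_rays` x `radius` numeric matrix (Gamma_k).
#' @export
polar_unwrap <- function(W, centroid, config = picking_config()) {
  ri <- ray_indices(centroid, dim(W), config$n_rays, config$radius)
  vals <- W[cbind(as.vector(ri$rows), as.vector(ri$cols))]
  g <- matrix(vals, config$n_rays, config$radius)
  g[is.na(g)] <- 0
  g
}

#' Cepstrum-based acceptance of a polar patch
#'
#' Computes the cepstrum `C_k = log |F(Gamma_k)|` of the polar-unwrapped
#' patch (magnitudes floored at 1e-8 before the log) and asserts the
#' model's realness constraint: the inverse transform of `C_k` must be
#' pure real, which holds for any real patch because `log|F|` is
#' even-symmetric. The acceptance score measures angular coherence: the
#' fraction of non-DC spectral energy of the patch at angular frequency
#' zero. A closed border is present at every angle, so its energy
#' concentrates in the angularly constant component; incoherent noise
#' spreads energy over all angular frequencies. A constant patch has no
#' non-DC energy and scores 0.
#'
#' @param gamma n_rays x radius numeric matrix.
#' @param config a [picking_config()] (supplies the threshold).
#' @return List with `score`, `accepted`, `cepstrum` (the matrix C_k) and
#'   `max_imag_ratio` (realness check residual).
#' @export
cepstrum_accept <- function(gamma, config = picking_config()) {
  if (any(!is.finite(gamma))) stop("polar patch must be finite", call. = FALSE)
  Fg <- fft(gamma)
  C <- log(pmax(Mod(Fg), 1e-8))
  # realness constraint of the cepstrum model
  inv <- fft(C, inverse = TRUE) / length(C)
  max_real <- max(abs(Re(inv)))
  imag_ratio <- if (max_real > 0) max(abs(Im(inv))) / max_real else 0
  P <- Mod(Fg)^2
  tot <- sum(P) - P[1L, 1L]
  if (tot <= 0) {
    score <- 0
  } else {
    score <- (sum(P[1L, ]) - P[1L, 1L]) / tot  # angular frequency 0 row
  }
  list(score = score,
       accepted = score >= config$cepstrum_accept_threshold,
       cepstrum = C, max_imag_ratio = imag_ratio)
}
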