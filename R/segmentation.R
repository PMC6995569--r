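#' Erase the interior of a region mask
#'
#' Removes pixels whose full 8-neighbourhood is foreground (the
#' morphological interior under a 3x3 structuring element), leaving a
#' 1-2 px border band. This realizes the internal-polygon erasure step
#' deterministically and parameter-free.
#'
#' @param mask logical matrix containing the candidate's pixels.
#' @return Logical matrix: the border band.
#' @export
erase_interior <- function(mask) {
  storage.mode(mask) <- "integer"
  if (!any(mask == 1L)) return(mask == 1L)
  interior <- EBImage::erode(mask, matrix(1L, 3L, 3L))
  mask == 1L & !(interior == 1L)
}

#' Geodesic distance map from a region centroid
#'
#' Chamfer shortest-path distances (8-neighbour steps, cost 1 axial and
#' sqrt(2) diagonal) from the source through the traversable domain, which
#' is the complement of the barrier (border) pixels. Barrier pixels and
#' pixels unreachable from the source stay `+Inf`; a closed border thus
#' isolates its interior pocket, and an open border forces paths through
#' the gap, inflating distances beyond the Euclidean ones. That inflation
#' is what lets a distance cap close open borders.
#'
#' @param barrier logical matrix of border pixels.
#' @param source numeric `(row, col)`, 0-based; must not be a barrier pixel.
#' @return A `GeodesicMap`: list with `distances` (matrix, `+Inf` =
#'   unreachable) and `source`.
#' @export
geodesic_map <- function(barrier, source) {
  storage.mode(barrier) <- "logical"
  sr <- as.integer(round(source[1])); sc <- as.integer(round(source[2]))
  if (sr < 0L || sr >= nrow(barrier) || sc < 0L || sc >= ncol(barrier))
    stop("source outside grid", call. = FALSE)
  if (barrier[sr + 1L, sc + 1L])
    stop("source lies on a border pixel", call. = FALSE)
  structure(list(distances = geodesic_cpp(barrier, sr, sc),
                 source = c(sr, sc)),
            class = "GeodesicMap")
}

#' Extract the region boundary from the geodesic map
#'
#' Caps the geodesic map at the critical distance `D =
#' multiplier * median(d[d > 0])` over the rays with border evidence, and
#' traces the outer contour of the level set `{g <= D}` as a closed,
#' ordered curve. For a closed border the enclosure itself caps the
#' region, so the traced curve follows the border; for an open border the
#' geodesic leakage through the gap exceeds `D` locally, which closes the
#' gap.
#'
#' @param geo a [geodesic_map()].
#' @param border_distances integer vector of per-ray border distances
#'   (from [radial_profiles()]); all zero means no border evidence and the
#'   candidate is rejected (`NULL` return).
#' @param multiplier critical-distance multiplier (default 3).
#' @return A `BoundaryCurve` (list with `points`, an ordered closed
#'   Nx2 matrix of 0-based `(row, col)`, and `is_closed = TRUE`), or
#'   `NULL` when there is no border evidence or the level set is
#'   degenerate (< 8 boundary points).
#' @export
extract_boundary <- function(geo, border_distances, multiplier = 3) {
  d <- border_distances[border_distances > 0]
  if (length(d) == 0L) return(NULL)
  D <- multiplier * median(d)
  mask <- is.finite(geo$distances) & geo$distances <= D
  if (sum(mask) < 8L) return(NULL)
  pts <- trace_outer_contour(mask)
  if (is.null(pts) || nrow(pts) < 8L) return(NULL)
  structure(list(points = pts, is_closed = TRUE), class = "BoundaryCurve")
}

# Outer contour of the largest connected component of a mask, via
# EBImage::ocontour; returns 0-based (row, col) ordered points.
trace_outer_contour <- function(mask) {
  lab <- label_components(mask, 8L)
  if (max(lab) == 0L) return(NULL)
  if (max(lab) > 1L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    lab <- matrix(as.integer(lab == which.max(areas)), nrow(lab), ncol(lab))
  } else lab <- matrix(as.integer(lab > 0L), nrow(lab), ncol(lab))
  co <- EBImage::ocontour(lab)
  if (length(co) == 0L) return(NULL)
  pts <- co[[1L]]
  cbind(row = pts[, 1L], col = pts[, 2L])
}

#' Fourier descriptor smoothing of a closed boundary
#'
#' Represents the closed curve as a complex sequence `z = col + i row`,
#' removes the centroid, and keeps the smallest symmetric set of
#' lowest-frequency DFT coefficients whose cumulative energy reaches
#' `energy_fraction` of the total (the centroid term is excluded from the
#' energy accounting); all other coefficients are zeroed and the curve is
#' rebuilt by the inverse DFT. Truncation acts as a shape low-pass filter:
#' the coarse outline is kept and boundary noise removed.
#'
#' @param boundary a `BoundaryCurve`.
#' @param energy_fraction fraction of spectral energy to retain
#'   (default 0.98).
#' @return A smoothed `BoundaryCurve` with attributes
#'   `retained_energy_fraction` and `n_harmonics` (retained frequency
#'   pairs).
#' @export
fourier_smooth <- function(boundary, energy_fraction = 0.98) {
  if (!isTRUE(boundary$is_closed))
    stop("boundary must be a closed curve", call. = FALSE)
  pts <- boundary$points
  N <- nrow(pts)
  if (N < 8L) stop("need at least 8 boundary points", call. = FALSE)
  z <- complex(real = pts[, 2L], imaginary = pts[, 1L])
  ctr <- mean(z)
  Z <- fft(z - ctr)
  E <- Mod(Z)^2
  E[1L] <- 0 # centroid term excluded
  total <- sum(E)
  if (total == 0) return(boundary)
  folded <- pmin(seq_len(N) - 1L, N - (seq_len(N) - 1L))
  keep <- rep(FALSE, N); keep[1L] <- TRUE
  cum <- 0; kmax <- 0L
  for (f in sort(unique(folded[folded > 0L]))) {
    sel <- folded == f
    keep[sel] <- TRUE
    cum <- cum + sum(E[sel])
    kmax <- kmax + 1L
    if (cum >= energy_fraction * total) break
  }
  Z[!keep] <- 0
  z2 <- fft(Z, inverse = TRUE) / N + ctr
  out <- structure(list(points = cbind(row = Im(z2), col = Re(z2)),
                        is_closed = TRUE), class = "BoundaryCurve")
  attr(out, "retained_energy_fraction") <- cum / total
  attr(out, "n_harmonics") <- kmax
  out
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic with the ellipse-specific constraint `4AC - B^2 = 1`
#' (direct least-squares fitting), using the numerically stable
#' partitioned eigen-solution, followed by one robustness pass: points
#' whose absolute algebraic residual exceeds twice the median absolute
#' residual are discarded and the ellipse refit when at least five points
#' remain.
#'
#' @param points Nx2 matrix of `(row, col)` coordinates (N >= 5, not
#'   collinear), or a `BoundaryCurve`.
#' @param outlier_pass logical; run the residual-based rejection pass.
#' @return An `EllipseParams`: list with `center` (`(cx, cy)` = (col,
#'   row) px), `a` (semi-major), `b` (semi-minor), `angle` (radians in
#'   `[0, pi)`; 0 for a circle by convention), `n_points_used`.
#' @export
fit_ellipse <- function(points, outlier_pass = TRUE) {
  if (inherits(points, "BoundaryCurve")) points <- points$points
  if (nrow(points) < 5L) stop("need at least 5 points", call. = FALSE)
  x <- points[, 2L]; y <- points[, 1L]
  fit <- fit_ellipse_direct(x, y)
  if (outlier_pass) {
    res <- abs(conic_residual(fit$conic, x, y))
    mad <- median(res)
    keep <- if (mad > 0) res <= 2 * mad else rep(TRUE, length(res))
    if (sum(keep) >= 5L && sum(keep) < length(res)) {
      fit <- fit_ellipse_direct(x[keep], y[keep])
    }
    n_used <- sum(keep)
  } else n_used <- length(x)
  out <- conic_to_ellipse(fit$conic)
  out$n_points_used <- n_used
  out
}

# Halir & Flusser partitioned solution of Fitzgibbon's direct LSQ fit
fit_ellipse_direct <- function(x, y) {
  mx <- mean(x); my <- mean(y); s <- max(sd(x), sd(y), 1e-12)
  xs <- (x - mx) / s; ys <- (y - my) / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point configuration (collinear?)", call. = FALSE))
  M <- S1 + S2 %*% T3
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)   # inv(C1) %*% M
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)  # exactly one eigenvector satisfies the constraint
  if (length(ok) == 0L)
    stop("no ellipse solution for these points", call. = FALSE)
  a1 <- vecs[, ok[1L]]
  coef <- c(a1, T3 %*% a1)  # (A, B, C, D, E, F) in scaled frame
  # undo the normalization x = (X - mx)/s, y = (Y - my)/s
  A <- coef[1] / s^2; B <- coef[2] / s^2; C <- coef[3] / s^2
  D <- coef[4] / s - (2 * coef[1] * mx + coef[2] * my) / s^2
  E <- coef[5] / s - (coef[2] * mx + 2 * coef[3] * my) / s^2
  F <- coef[6] + (coef[1] * mx^2 + coef[2] * mx * my + coef[3] * my^2) / s^2 -
    (coef[4] * mx + coef[5] * my) / s
  list(conic = c(A = A, B = B, C = C, D = D, E = E, F = F))
}

conic_residual <- function(conic, x, y) {
  conic[1] * x^2 + conic[2] * x * y + conic[3] * y^2 +
    conic[4] * x + conic[5] * y + conic[6]
}

# geometric parameters from conic coefficients, via the eigensystem of the
# quadratic-form matrix [[A, B/2], [B/2, C]]
conic_to_ellipse <- function(conic) {
  A <- conic[1]; B <- conic[2]; C <- conic[3]
  D <- conic[4]; E <- conic[5]; F <- conic[6]
  disc <- B^2 - 4 * A * C
  if (disc >= 0) stop("conic is not an ellipse", call. = FALSE)
  ctr <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), c(-D, -E))
  cx <- ctr[1]; cy <- ctr[2]
  Fc <- conic_residual(conic, cx, cy)  # conic value at the centre
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  if (Fc > 0) { Q <- -Q; Fc <- -Fc }   # orient so that -Fc/lambda > 0
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values                      # descending; both > 0 for an ellipse
  if (any(lam <= 0) || Fc >= 0) stop("conic is not an ellipse", call. = FALSE)
  a <- sqrt(-Fc / lam[2]); b <- sqrt(-Fc / lam[1])  # smaller lambda = major
  if (abs(a - b) < 1e-9 * max(a, 1)) {
    theta <- 0 # circle: angle fixed at 0 by convention
  } else {
    v <- eg$vectors[, 2]                # major-axis direction (x, y)
    theta <- atan2(v[2], v[1]) %% pi
  }
  structure(list(center = c(cx = unname(cx), cy = unname(cy)),
                 a = unname(a), b = unname(b), angle = unname(theta)),
            class = "EllipseParams")
}

#' @export
print.EllipseParams <- function(x, ...) {
  cat(sprintf("Ellipse: center (%.2f, %.2f), a = %.2f, b = %.2f, angle = %.1f deg\n",
              x$center[1], x$center[2], x$a, x$b, x$angle * 180 / pi))
  invisible(x)
}

#' Classify a particle view from its ellipse aspect ratio
#'
#' Annular top views are near-circular; barrel-shaped side views are
#' elongated. The view is `"top"` when `a/b < threshold` and `"side"`
#' otherwise (the threshold value itself is assigned to the elongated
#' class).
#'
#' @param ellipse an `EllipseParams`.
#' @param view_aspect_threshold aspect-ratio cut (default 1.5).
#' @return `"top"` or `"side"`.
#' @export
classify_view <- function(ellipse, view_aspect_threshold = 1.5) {
  if (ellipse$a / ellipse$b < view_aspect_threshold) "top" else "side"
}
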