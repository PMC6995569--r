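# Phantom builders and independent oracles shared across the test files.

# filled disk mask on an m x n grid (centre/radius in 1-based pixels)
disk_mask <- function(m, n, cr, cc, radius) {
  r <- matrix(seq_len(m), m, n)
  c <- matrix(seq_len(n), m, n, byrow = TRUE)
  sqrt((r - cr)^2 + (c - cc)^2) <= radius
}

# annulus (ring band) mask
ring_mask <- function(m, n, cr, cc, r_in, r_out) {
  r <- matrix(seq_len(m), m, n)
  c <- matrix(seq_len(n), m, n, byrow = TRUE)
  rad <- sqrt((r - cr)^2 + (c - cc)^2)
  rad >= r_in & rad <= r_out
}

# axis-aligned filled rectangle mask
rect_mask <- function(m, n, r0, c0, h, w) {
  out <- matrix(FALSE, m, n)
  out[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
  out
}

# points sampled from an ellipse: centre (cx, cy) = (col, row), semi-axes
# a >= b, rotation theta; returns (row, col) matrix
ellipse_points <- function(n, cx, cy, a, b, theta) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  x <- cx + a * cos(t) * cos(theta) - b * sin(t) * sin(theta)
  y <- cy + a * cos(t) * sin(theta) + b * sin(t) * cos(theta)
  cbind(row = y, col = x)
}

# --- independent oracles ---------------------------------------------------

# one explicit Perona-Malik step, written as the literal 4-neighbour
# stencil with no-flux boundaries (independent of the package's C++ path)
pm_step_oracle <- function(img, K, dt) {
  m <- nrow(img); n <- ncol(img)
  out <- img
  g <- function(s) exp(-(s / K)^2)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    acc <- 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- i + d[1]; c <- j + d[2]
      if (r >= 1 && r <= m && c >= 1 && c <= n) {
        s <- img[r, c] - img[i, j]
        acc <- acc + g(s) * s
      }
    }
    out[i, j] <- img[i, j] + dt * acc
  }
  out
}

# exhaustive Otsu: try every 256-bin cut, compute between-class variance
# from first principles on the binned data
otsu_oracle <- function(image) {
  v <- as.vector(image)
  bins <- pmin(floor(v * 256), 255)
  best <- -Inf; best_cut <- NA
  for (cut in 1:255) {
    lo <- bins < cut; hi <- !lo
    if (!any(lo) || !any(hi)) next
    centers <- (bins + 0.5) / 256
    w0 <- mean(lo); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(centers[lo]) - mean(centers[hi]))^2
    if (sb > best + 1e-15) { best <- sb; best_cut <- cut }
  }
  best_cut / 256
}

# chamfer geodesic distances by iterated relaxation (Bellman-Ford style),
# independent of the package's Dijkstra
geodesic_oracle <- function(barrier, src_r, src_c) {
  m <- nrow(barrier); n <- ncol(barrier)
  d <- matrix(Inf, m, n)
  d[src_r + 1, src_c + 1] <- 0
  steps <- expand.grid(dr = -1:1, dc = -1:1)
  steps <- steps[!(steps$dr == 0 & steps$dc == 0), ]
  repeat {
    changed <- FALSE
    for (i in seq_len(m)) for (j in seq_len(n)) {
      if (barrier[i, j]) next
      for (k in seq_len(nrow(steps))) {
        r <- i + steps$dr[k]; c <- j + steps$dc[k]
        if (r < 1 || r > m || c < 1 || c > n || barrier[r, c]) next
        w <- if (steps$dr[k] == 0 || steps$dc[k] == 0) 1 else sqrt(2)
        if (d[r, c] + w < d[i, j] - 1e-12) { d[i, j] <- d[r, c] + w; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  d[barrier] <- Inf
  d
}

# recursive flood fill component count
flood_count_oracle <- function(mask, connectivity) {
  m <- nrow(mask); n <- ncol(mask)
  seen <- matrix(FALSE, m, n)
  nbr <- if (connectivity == 8) expand.grid(dr = -1:1, dc = -1:1)
         else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  count <- 0
  for (i0 in seq_len(m)) for (j0 in seq_len(n)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    count <- count + 1
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr$dr[k]; c <- p[2] + nbr$dc[k]
        if (r >= 1 && r <= m && c >= 1 && c <= n && mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# optimal (maximum) matching count under a distance cap, by exhaustive
# recursion over truth assignments; feasible for small fixtures only
optimal_match_count <- function(picks, truth, cap) {
  np <- nrow(picks); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(0L)
  dmat <- sqrt(outer(picks[, 1], truth[, 1], "-")^2 +
               outer(picks[, 2], truth[, 2], "-")^2)
  ok <- dmat <= cap
  best <- 0L
  rec <- function(p, used_t, count) {
    if (count + (np - p + 1) <= best) return()
    if (p > np) { best <<- max(best, count); return() }
    rec(p + 1, used_t, count)                 # leave pick p unmatched
    for (t in which(ok[p, ] & !used_t)) {
      used_t[t] <- TRUE
      rec(p + 1, used_t, count + 1L)
      used_t[t] <- FALSE
    }
  }
  rec(1L, rep(FALSE, nt), 0L)
  best
}
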