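#' Pipeline configuration
#'
#' Aggregates the per-stage configurations and the global seed. The
#' defaults are the method's working settings: 16 scale layers, K = 0.05,
#' rank-2 NNMF, an inclusive 100-1500 px area gate, ray radius 50 px, 98%
#' Fourier descriptor energy and a critical-distance multiplier of 3.
#'
#' @param scale_space a [scale_space_config()].
#' @param nnmf an [nnmf_config()].
#' @param picking a [picking_config()].
#' @param segmentation list with `energy_fraction`,
#'   `view_aspect_threshold`, `critical_distance_multiplier`.
#' @param evaluation list with `max_match_dist` (px).
#' @param seed integer; every random draw in the pipeline flows from it.
#' @param invert logical; invert intensities after normalization so that
#'   (conventionally dark) particles become bright structures.
#' @param log_level `"quiet"` or `"info"`.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(scale_space = scale_space_config(),
                            nnmf = nnmf_config(),
                            picking = picking_config(),
                            segmentation = list(energy_fraction = 0.98,
                                                view_aspect_threshold = 1.5,
                                                critical_distance_multiplier = 3),
                            evaluation = list(max_match_dist = 10),
                            seed = 1L, invert = TRUE,
                            log_level = c("quiet", "info")) {
  log_level <- match.arg(log_level)
  structure(list(scale_space = scale_space, nnmf = nnmf, picking = picking,
                 segmentation = segmentation, evaluation = evaluation,
                 seed = as.integer(seed), invert = invert,
                 log_level = log_level),
            class = "PipelineConfig")
}

#' Run the full picking and segmentation pipeline
#'
#' Executes the three phases in order: (I) interframe analysis (scale
#' family, Perona-Malik diffusion, Gaussian octaves, DOG stacking,
#' feature matrix); (II) rank-2 NNMF band separation, Otsu binarization,
#' size-gated candidate extraction and cepstrum filtering; (III) geodesic
#' border closing, Fourier descriptor smoothing, ellipse fitting and view
#' classification. Deterministic for a fixed config (the NNMF seed is
#' derived from the pipeline seed).
#'
#' @param mg a [micrograph()] or numeric matrix (raw intensities).
#' @param config a [pipeline_config()].
#' @return List of `ParticleRecord`s (each a list with `candidate`,
#'   `ellipse`, `view`, `boundary`), with attributes `channels` (the
#'   `ChannelPair`), `candidates` (all size-gated candidates),
#'   `n_candidates`, `n_accepted` and `timings` (seconds per phase).
#' @export
run_pipeline <- function(mg, config = pipeline_config()) {
  loginfo <- function(...) if (config$log_level == "info") message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  if (!inherits(mg, "Micrograph")) mg <- micrograph(as_pixels(mg))
  mg <- normalize_micrograph(mg, invert = config$invert)
  if (mg$degenerate) {
    warning("constant micrograph: nothing to pick")
    return(empty_records())
  }
  fm <- interframe_analysis(mg, config$scale_space)
  t1 <- proc.time()[["elapsed"]]
  loginfo("phase I: feature matrix %d x %d (%.1f s)",
          nrow(fm$values), ncol(fm$values), t1 - t0)

  nn_cfg <- config$nnmf
  nn_cfg$seed <- config$seed
  fp <- nnmf(fm, nn_cfg)
  ch <- do.call(assign_channels, reconstruct_channels(fp, fm$origin_shape))
  W1 <- rescale01(ch$W1); W2 <- rescale01(ch$W2)
  o1 <- otsu_threshold(W1); o2 <- otsu_threshold(W2)
  if (o1$degenerate || o2$degenerate) {
    warning("degenerate Otsu threshold on a constant channel; picking aborted")
    return(empty_records(channels = ch))
  }
  cands <- extract_candidates(o1$binary, o2$binary, W2, config$picking)
  labels <- attr(cands, "label_matrix")
  t2 <- proc.time()[["elapsed"]]
  loginfo("phase II: %d candidates, %d accepted by cepstrum (%.1f s)",
          length(cands), sum(vapply(cands, `[[`, TRUE, "accepted")), t2 - t1)

  records <- segment_candidates(cands, labels, o1$binary, W2,
                                config$picking, config$segmentation)
  t3 <- proc.time()[["elapsed"]]
  loginfo("phase III: %d particles segmented (%.1f s)", length(records), t3 - t2)
  attr(records, "channels") <- ch
  attr(records, "candidates") <- cands
  attr(records, "n_candidates") <- length(cands)
  attr(records, "n_accepted") <- length(records)
  attr(records, "timings") <- c(phase1 = t1 - t0, phase2 = t2 - t1,
                                phase3 = t3 - t2)
  records
}

empty_records <- function(channels = NULL) {
  r <- list()
  attr(r, "channels") <- channels
  attr(r, "n_candidates") <- 0L
  attr(r, "n_accepted") <- 0L
  r
}

rescale01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi > lo) (x - lo) / (hi - lo) else x * 0
}

#' Phase III segmentation of accepted candidates
#'
#' For every cepstrum-accepted candidate: crop a window around its
#' centroid, erase the interior of its component to a border band, map
#' geodesic distances from the centroid, extract and smooth the boundary,
#' fit the ellipse and classify the view. Candidates without border
#' evidence are dropped; a degenerate ellipse fit falls back to the
#' region's second-moment ellipse so a picked particle is not lost to a
#' fitting failure.
#'
#' @param candidates list of `RegionCandidate`s (see
#'   [extract_candidates()]).
#' @param label_matrix integer label image the candidates refer to.
#' @param B1 logical structure binary (border-distance source).
#' @param W2 numeric channel image.
#' @param picking a [picking_config()].
#' @param segmentation list with `energy_fraction`,
#'   `view_aspect_threshold`, `critical_distance_multiplier`.
#' @return List of `ParticleRecord`s.
#' @export
segment_candidates <- function(candidates, label_matrix, B1, W2,
                               picking = picking_config(),
                               segmentation = list(energy_fraction = 0.98,
                                                   view_aspect_threshold = 1.5,
                                                   critical_distance_multiplier = 3)) {
  m <- nrow(label_matrix); n <- ncol(label_matrix)
  records <- list()
  for (cand in candidates) {
    if (!isTRUE(cand$accepted)) next
    # crop window around the centroid
    pad <- picking$radius + 8L
    r0 <- max(0L, floor(cand$centroid[1]) - pad)
    c0 <- max(0L, floor(cand$centroid[2]) - pad)
    r1 <- min(m, ceiling(cand$centroid[1]) + pad + 1L)
    c1 <- min(n, ceiling(cand$centroid[2]) + pad + 1L)
    rows <- (r0 + 1L):r1; cols <- (c0 + 1L):c1
    mask <- label_matrix[rows, cols, drop = FALSE] == cand$label
    if (!any(mask)) next
    border <- erase_interior(mask)
    src <- cand$centroid - c(r0, c0)
    # the geodesic source must sit in the pocket the border encloses: for a
    # solid component that is its eroded interior, for an annulus the hole
    src <- nudge_off_barrier(border, src, prefer = mask & !border)
    if (is.null(src)) next
    geo <- geodesic_map(border, src)
    d <- cand$border_distances
    if (all(d == 0)) {
      # no border evidence in B1; fall back to the component's own border
      d <- radial_profiles(label_matrix == cand$label,
                           cand$centroid, picking)$border_distances
    }
    boundary <- extract_boundary(geo, d,
                                 segmentation$critical_distance_multiplier)
    if (is.null(boundary)) next
    smooth <- fourier_smooth(boundary, segmentation$energy_fraction)
    ellipse <- tryCatch(fit_ellipse(smooth),
                        error = function(e) moment_ellipse(mask))
    if (is.null(ellipse)) next
    # back to global frame
    ellipse$center <- c(cx = unname(ellipse$center["cx"]) + c0,
                        cy = unname(ellipse$center["cy"]) + r0)
    smooth$points[, 1L] <- smooth$points[, 1L] + r0
    smooth$points[, 2L] <- smooth$points[, 2L] + c0
    view <- classify_view(ellipse, segmentation$view_aspect_threshold)
    records[[length(records) + 1L]] <-
      structure(list(candidate = cand, ellipse = ellipse, view = view,
                     boundary = smooth),
                class = "ParticleRecord")
  }
  records
}

# move the geodesic source to the nearest suitable pixel when the centroid
# falls on the border band; cells flagged in `prefer` (the enclosed pocket)
# are searched first so the source never escapes to the open background.
# NULL when nothing suitable exists nearby.
nudge_off_barrier <- function(barrier, src, prefer = NULL) {
  sr <- as.integer(round(src[1])); sc <- as.integer(round(src[2]))
  m <- nrow(barrier); n <- ncol(barrier)
  sr <- min(max(sr, 0L), m - 1L); sc <- min(max(sc, 0L), n - 1L)
  if (!barrier[sr + 1L, sc + 1L] &&
      (is.null(prefer) || prefer[sr + 1L, sc + 1L]))
    return(c(sr, sc))
  search <- function(ok, max_rad) {
    for (rad in seq_len(max_rad)) {
      win <- expand.grid(r = (sr - rad):(sr + rad), c = (sc - rad):(sc + rad))
      win <- win[win$r >= 0 & win$r < m & win$c >= 0 & win$c < n, ]
      good <- ok[cbind(win$r + 1L, win$c + 1L)]
      if (any(good)) {
        dd <- (win$r - src[1])^2 + (win$c - src[2])^2
        dd[!good] <- Inf
        k <- which.min(dd)
        return(c(win$r[k], win$c[k]))
      }
    }
    NULL
  }
  if (!is.null(prefer)) {
    hit <- search(prefer & !barrier, 15L)
    if (!is.null(hit)) return(hit)
  }
  if (!barrier[sr + 1L, sc + 1L]) return(c(sr, sc))
  search(!barrier, 5L)
}

# second-moment fallback ellipse of a filled mask (0-based local frame)
moment_ellipse <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 5L) return(NULL)
  xy <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  ctr <- colMeans(xy)
  C <- stats::cov(xy)
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-6)
  a <- 2 * sqrt(lam[1]); b <- 2 * sqrt(lam[2])
  theta <- if (abs(a - b) < 1e-9) 0 else atan2(eg$vectors[2, 1], eg$vectors[1, 1]) %% pi
  structure(list(center = c(cx = unname(ctr["x"]), cy = unname(ctr["y"])),
                 a = a, b = b, angle = theta, n_points_used = nrow(idx)),
            class = "EllipseParams")
}

#' Picked coordinates of a record list
#'
#' @param records output of [run_pipeline()].
#' @return Data.frame with `row`, `col` (ellipse centres) and `view`.
#' @export
pick_coordinates <- function(records) {
  if (length(records) == 0L)
    return(data.frame(row = numeric(), col = numeric(), view = character()))
  do.call(rbind, lapply(records, function(p) data.frame(
    row = unname(p$ellipse$center["cy"]), col = unname(p$ellipse$center["cx"]),
    view = p$view)))
}
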