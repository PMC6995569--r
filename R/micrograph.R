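#' Micrograph container
#'
#' A `Micrograph` wraps a 2D real-valued intensity field together with
#' optional pixel-size metadata. All pipeline stages operate on this class;
#' intensities are expected to be normalized to `[0, 1]` (see
#' [normalize_micrograph()]) before entering the scale-space stage.
#'
#' @param pixels numeric matrix of intensities (m rows x n columns), m, n >= 8.
#' @param pixel_size_angstrom optional positive scalar, physical pixel size.
#' @param source_path optional character, provenance of the image.
#' @return An object of class `Micrograph`: a list with elements `pixels`,
#'   `pixel_size_angstrom`, `source_path`, `normalized` (logical) and
#'   `degenerate` (logical; set when a constant image was normalized).
#' @examples
#' mg <- micrograph(matrix(runif(64 * 64), 64, 64))
#' dim(mg$pixels)
#' @export
micrograph <- function(pixels, pixel_size_angstrom = NULL, source_path = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("micrograph must be at least 8 x 8 pixels", call. = FALSE)
  if (!is.null(pixel_size_angstrom) && pixel_size_angstrom <= 0)
    stop("`pixel_size_angstrom` must be positive", call. = FALSE)
  structure(
    list(pixels = pixels,
         pixel_size_angstrom = pixel_size_angstrom,
         source_path = source_path,
         normalized = FALSE,
         degenerate = FALSE),
    class = "Micrograph")
}

#' @export
print.Micrograph <- function(x, ...) {
  cat(sprintf("Micrograph: %d x %d px", nrow(x$pixels), ncol(x$pixels)))
  if (!is.null(x$pixel_size_angstrom))
    cat(sprintf(", %.3f A/px", x$pixel_size_angstrom))
  if (x$normalized) cat(" [normalized]")
  if (x$degenerate) cat(" [degenerate]")
  cat(sprintf("\n  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Normalize micrograph intensities to the unit interval
#'
#' Affinely rescales intensities so that the minimum maps to 0 and the
#' maximum to 1. A constant image cannot be rescaled; it maps to all zeros
#' and the `degenerate` flag is set.
#'
#' @param mg a [micrograph()] object or a plain numeric matrix.
#' @param invert logical; if `TRUE` the normalized image is flipped to
#'   `1 - x`. Cryo-EM particles are darker than the background, so the
#'   pipeline inverts by default at entry to make structures bright.
#' @return A normalized `Micrograph` (intensities in `[0, 1]`).
#' @examples
#' mg <- normalize_micrograph(matrix(c(0, 255), 8, 8))
#' range(mg$pixels)
#' @export
normalize_micrograph <- function(mg, invert = FALSE) {
  if (is.matrix(mg)) mg <- micrograph(mg)
  px <- mg$pixels
  if (any(!is.finite(px)))
    stop("micrograph contains non-finite pixels", call. = FALSE)
  lo <- min(px); hi <- max(px)
  if (hi > lo) {
    px <- (px - lo) / (hi - lo)
  } else {
    px[] <- 0
    mg$degenerate <- TRUE
  }
  if (invert && !mg$degenerate) px <- 1 - px
  mg$pixels <- px
  mg$normalized <- TRUE
  mg
}

as_pixels <- function(x) {
  if (inherits(x, "Micrograph")) x$pixels else x
}
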