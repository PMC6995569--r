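#' Read a micrograph from MRC, TIFF or PNG
#'
#' MRC files must be single 2D sections in mode 0 (int8), 1 (int16) or
#' 2 (float32); the pixel size is propagated from the cell header when
#' present. TIFF and PNG are read through the `tiff` and `png` packages.
#'
#' @param path file path; format chosen by extension (`.mrc`, `.tif`,
#'   `.tiff`, `.png`).
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    mrc = read_mrc(path),
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(x)) == 3L) x <- x[, , 1L]
      list(pixels = x, pixel_size = NULL)
    },
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3L) x <- x[, , 1L]
      list(pixels = x, pixel_size = NULL)
    },
    stop("unknown micrograph format: .", ext, " (", path, ")", call. = FALSE))
  micrograph(px$pixels, pixel_size_angstrom = px$pixel_size, source_path = path)
}

# Minimal MRC2014 2D reader: modes 0/1/2, little- or big-endian via the
# machine stamp / sanity check on nx.
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L)
    stop("truncated MRC header in ", path, call. = FALSE)
  parse_ints <- function(endian) readBin(hdr_raw, "integer", n = 10L,
                                         size = 4L, endian = endian)
  endian <- "little"
  ints <- parse_ints(endian)
  if (ints[1] <= 0 || ints[1] > 1e6) {
    endian <- "big"
    ints <- parse_ints(endian)
  }
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  if (nx <= 0 || ny <= 0 || nz <= 0)
    stop("corrupt MRC header in ", path, call. = FALSE)
  if (nz != 1L)
    stop("MRC stack with nz=", nz, " sections; only 2D images are supported (",
         path, ")", call. = FALSE)
  if (!mode %in% c(0L, 1L, 2L))
    stop("unsupported MRC mode ", mode, " in ", path, call. = FALSE)
  # cell dimensions (floats at words 11-13) and grid size (words 8-10)
  floats <- readBin(hdr_raw[41:52], "numeric", n = 3L, size = 4L, endian = endian)
  mx <- ints[8]
  pixel_size <- if (mx > 0 && floats[1] > 0) floats[1] / mx else NULL
  n_px <- nx * ny
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n_px, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n_px, size = 2L,
                             signed = TRUE, endian = endian)),
    "2" = readBin(con, "numeric", n = n_px, size = 4L, endian = endian))
  if (length(data) < n_px)
    stop("truncated MRC data section in ", path, call. = FALSE)
  # MRC stores rows (columns along x, fastest) -> fill by column then transpose
  list(pixels = t(matrix(data, nrow = nx, ncol = ny)), pixel_size = pixel_size)
}

#' Write a micrograph as MRC (mode 2, float32)
#'
#' @param mg a [micrograph()] or numeric matrix.
#' @param path output path.
#' @param pixel_size_angstrom optional pixel size stored in the cell header.
#' @return Invisibly, `path`.
#' @export
write_mrc <- function(mg, path, pixel_size_angstrom = NULL) {
  px <- as_pixels(mg)
  if (inherits(mg, "Micrograph") && is.null(pixel_size_angstrom))
    pixel_size_angstrom <- mg$pixel_size_angstrom
  m <- nrow(px); n <- ncol(px)
  con <- file(path, "wb")
  on.exit(close(con))
  apx <- if (is.null(pixel_size_angstrom)) 1 else pixel_size_angstrom
  writeBin(as.integer(c(n, m, 1L, 2L, 0L, 0L, 0L, n, m, 1L)), con,
           size = 4L, endian = "little")
  writeBin(as.numeric(c(n * apx, m * apx, apx, 90, 90, 90)), con,
           size = 4L, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(min(px), max(px), mean(px))), con,
           size = 4L, endian = "little")
  # ispg, nsymbt, extra (25 words), origin, map, machst, rms, nlabl + labels
  writeBin(as.integer(rep(0L, 2L)), con, size = 4L, endian = "little")
  writeBin(as.integer(rep(0L, 25L)), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4L, endian = "little")
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.integer(c(16708L)), con, size = 4L, endian = "little") # 0x44 0x41 machine stamp
  writeBin(as.numeric(sd(px)), con, size = 4L, endian = "little")
  writeBin(as.integer(rep(0L, 1L + 200L)), con, size = 4L, endian = "little")
  writeBin(as.numeric(t(px)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Write picked particles to .box, .star or .csv
#'
#' `box` follows the EMAN convention: one line `x y w h` with the box's
#' lower-left corner in a bottom-left-origin frame, the box size being
#' `2*ceiling(a) + 4`. `star` writes a coordinate loop with
#' `rlnCoordinateX/rlnCoordinateY` in a top-left-origin frame (x = col).
#' `csv` writes the full particle table (centre, semi-axes, angle in
#' degrees, view, cepstrum score).
#'
#' @param particles list of `ParticleRecord`s from [run_pipeline()].
#' @param path output path.
#' @param format `"box"`, `"star"` or `"csv"`.
#' @param image_height image height in px (rows); required for the .box
#'   bottom-left flip.
#' @return Invisibly, `path`.
#' @export
write_picks <- function(particles, path, format = c("csv", "box", "star"),
                        image_height = NULL) {
  format <- match.arg(format)
  df <- particles_table(particles)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE)
  } else if (format == "box") {
    if (is.null(image_height))
      stop("image_height is required for .box output", call. = FALSE)
    lines <- character(nrow(df))
    if (nrow(df) > 0L) for (i in seq_len(nrow(df))) {
      bs <- 2L * ceiling(df$a[i]) + 4L
      x <- round(df$col[i] - bs / 2)
      y_top <- round(df$row[i] - bs / 2)
      y <- image_height - 1 - y_top - bs  # flip to bottom-left origin
      lines[i] <- sprintf("%d\t%d\t%d\t%d", as.integer(x), as.integer(y),
                          bs, bs)
    }
    writeLines(lines, path)
  } else { # star
    hdr <- c("", "data_", "", "loop_", "_rlnCoordinateX #1", "_rlnCoordinateY #2")
    body <- if (nrow(df) > 0L)
      sprintf("%.4f %.4f", df$col, df$row) else character(0)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

particles_table <- function(particles) {
  if (length(particles) == 0L)
    return(data.frame(row = numeric(), col = numeric(), a = numeric(),
                      b = numeric(), theta_deg = numeric(),
                      view = character(), area = integer(),
                      cepstrum_score = numeric()))
  do.call(rbind, lapply(particles, function(p) data.frame(
    row = p$ellipse$center["cy"], col = p$ellipse$center["cx"],
    a = p$ellipse$a, b = p$ellipse$b,
    theta_deg = p$ellipse$angle * 180 / pi, view = p$view,
    area = p$candidate$area, cepstrum_score = p$candidate$cepstrum_score,
    row.names = NULL)))
}

#' Read pick or truth coordinates from CSV or EMAN .box
#'
#' CSV files must contain `row` and `col` columns (the simulator's truth
#' CSV and [write_picks()] CSV both qualify). For `.box` files the box
#' centre is recovered and the y axis flipped back to top-left origin,
#' which requires `image_height`.
#'
#' @param path input file.
#' @param image_height image height in px for .box input.
#' @return Data.frame with `row` and `col` columns.
#' @export
read_coords <- function(path, image_height = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "box") {
    if (is.null(image_height))
      stop("image_height is required for .box input", call. = FALSE)
    df <- read.table(path, col.names = c("x", "y", "w", "h"))
    data.frame(row = image_height - 1 - df$y - df$h + df$h / 2,
               col = df$x + df$w / 2)
  } else {
    df <- read.csv(path)
    if (!all(c("row", "col") %in% names(df)))
      stop("CSV must contain `row` and `col` columns: ", path, call. = FALSE)
    df[, c("row", "col"), drop = FALSE]
  }
}
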