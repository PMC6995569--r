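#' Write a pipeline configuration to an INI-style text file
#'
#' Plain-text `key = value` pairs grouped into one `[section]` per module
#' plus a `[global]` section; [read_pipeline_config()] restores the exact
#' configuration (lossless roundtrip).
#'
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    if (is.numeric(v)) return(format(v, digits = 17, scientific = FALSE))
    as.character(v)
  }
  lines <- character(0)
  sec <- function(name, x) {
    lines <<- c(lines, sprintf("[%s]", name))
    for (k in names(x)) lines <<- c(lines, sprintf("%s = %s", k, fmt(x[[k]])))
    lines <<- c(lines, "")
  }
  sec("scale_space", unclass(config$scale_space))
  sec("nnmf", unclass(config$nnmf))
  sec("picking", unclass(config$picking))
  sec("segmentation", config$segmentation)
  sec("evaluation", config$evaluation)
  sec("global", list(seed = config$seed, invert = config$invert,
                     log_level = config$log_level))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration from an INI-style text file
#'
#' @param path file written by [write_pipeline_config()] (or hand-edited
#'   in the same format; unknown keys are rejected).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, ";")]
  sections <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      cur <- sub("^\\[(.*)\\]$", "\\1", ln)
      sections[[cur]] <- list()
    } else {
      if (is.null(cur)) stop("key outside any [section]: ", ln, call. = FALSE)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2L) stop("malformed line: ", ln, call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      sections[[cur]][[key]] <- parse_ini_value(val)
    }
  }
  getsec <- function(name) if (is.null(sections[[name]])) list() else sections[[name]]
  g <- getsec("global")
  as_int <- function(x) if (is.null(x)) x else as.integer(x)
  ss <- getsec("scale_space"); nn <- getsec("nnmf"); pk <- getsec("picking")
  pipeline_config(
    scale_space = do.call(scale_space_config, utils::modifyList(ss, list(
      n_scales = as_int(ss$n_scales),
      pm_iters_per_scale = as_int(ss$pm_iters_per_scale),
      scales_per_octave = as_int(ss$scales_per_octave)))),
    nnmf = do.call(nnmf_config, utils::modifyList(nn, list(
      rank = as_int(nn$rank), max_iter = as_int(nn$max_iter),
      seed = as_int(nn$seed)))),
    picking = do.call(picking_config, utils::modifyList(pk, list(
      area_min = as_int(pk$area_min), area_max = as_int(pk$area_max),
      radius = as_int(pk$radius), n_rays = as_int(pk$n_rays),
      connectivity = as_int(pk$connectivity)))),
    segmentation = getsec("segmentation"),
    evaluation = getsec("evaluation"),
    seed = if (is.null(g$seed)) 1L else as.integer(g$seed),
    invert = if (is.null(g$invert)) TRUE else g$invert,
    log_level = if (is.null(g$log_level)) "quiet" else g$log_level)
}

parse_ini_value <- function(v) {
  if (v %in% c("true", "false")) return(v == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}
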