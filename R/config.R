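## Pipeline defaults and plain-text configuration.

#' Default pipeline parameters
#'
#' Central defaults used across the pipeline. `anisotropy` is the
#' conductivity parameter pair of the curvature-aware operator (mm units;
#' chosen so the eigenfunction zero sets lock onto ridge lines on the
#' phantom); `N` x `M` is the mid-surface grid (40 x 20 by convention);
#' `sMax` bounds the curvature-alignment shift in grid cells; `q` is the
#' false-discovery-rate level.
#'
#' @return named list of defaults.
#' @export
hipposheetDefaults <- function() {
  list(
    dialect = "freesurfer",
    closureIterations = 2L,
    smoothingIterations = 10L,
    implicitSigma = 1,
    anisotropy = c(8, 2),
    eigenK = 5L,
    N = 40L,
    M = 20L,
    guardDistance = 3,
    sMax = 5,
    q = 0.05,
    seed = 1L
  )
}

#' Read / write a pipeline configuration
#'
#' Plain-text `key = value` format; unknown keys are an error, missing keys
#' take the defaults. Numeric vector values (like `anisotropy`) are
#' comma-separated. Writing then reading a config reproduces it exactly.
#'
#' @param path file path.
#' @param config named list (for writing).
#' @return `readPipelineConfig`: the merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  def <- hipposheetDefaults()
  if (!file.exists(path))
    hsError("cli", "config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- def
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      hsError("cli", "malformed config line: '%s'", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(def))
      hsError("cli", "unknown config key: '%s'", key)
    proto <- def[[key]]
    out[[key]] <- if (is.character(proto)) val
      else if (is.integer(proto)) as.integer(val)
      else as.numeric(strsplit(val, ",")[[1]])
  }
  out
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  fmt <- vapply(config, function(v) paste(format(v, digits = 17),
                                          collapse = ","), character(1))
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}
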