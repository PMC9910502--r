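#' Write a profile as two-column delimited text
#'
#' Columns: position (mm) and I/I0 (or counts), one row per sample.
#'
#' @param profile An `intensity_profile` (or list with `x` and `values`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pbisim profile: position_mm value", con)
  utils::write.table(data.frame(profile$x, profile$values), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#'
#' @param path File path.
#' @param pitch Optional pitch override; default inferred from positions.
#' @return An `intensity_profile`.
#' @export
read_profile <- function(path, pitch = NULL) {
  d <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#")
  if (is.null(pitch)) pitch <- stats::median(diff(d[[1L]]))
  structure(list(x = d[[1L]], values = d[[2L]], pitch = pitch,
                 normalization_region = default_baseline(nrow(d))),
            class = "intensity_profile")
}

#' Write a count image as 16-bit grayscale TIFF with a sidecar scale file
#'
#' Counts are linearly mapped to the 16-bit range; the mapping
#' (`scale`, `offset` such that `counts = pixel * scale + offset`) is
#' recorded in `<path>.scale.txt` so the integer counts round-trip exactly
#' when the count range does not exceed 65535 distinct values.
#'
#' @param counts Numeric matrix (or vector, written as one row).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(counts, path) {
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1L)
  lo <- min(m); hi <- max(m)
  integerish <- max(abs(m - round(m))) < 1e-9
  scale <- if (hi <= lo) 1
           else if (integerish && hi - lo <= 65535) 1  # lossless for counts
           else (hi - lo) / 65535
  pix <- round((m - lo) / scale)
  tiff::writeTIFF(pix / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  writeLines(c("# counts = pixel_value * scale + offset",
               sprintf("scale\t%.17g", scale),
               sprintf("offset\t%.17g", lo)),
             paste0(path, ".scale.txt"))
  invisible(path)
}

#' Read a count image written by [write_image()]
#'
#' @param path TIFF path (sidecar `<path>.scale.txt` must exist).
#' @return Numeric matrix of counts.
#' @export
read_image <- function(path) {
  pix <- tiff::readTIFF(path) * 65535
  sc <- utils::read.table(paste0(path, ".scale.txt"), header = FALSE,
                          comment.char = "#", sep = "\t")
  vals <- stats::setNames(sc[[2L]], sc[[1L]])
  round(pix) * vals[["scale"]] + vals[["offset"]]
}

#' Write a flat report as JSON
#'
#' @param report Named list (scalars and short vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with sections `mode`, `scene`, `spectrum`,
#'   `geometry`, `grid`, `detector`, `output` (see [run_config()]).
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a run configuration as YAML
#'
#' `read_config(write_config(cfg, path))` is idempotent.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
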