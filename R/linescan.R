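#' Line-scan image container
#'
#' A raw confocal line-scan (X-T) image: a space-by-time matrix of
#' fluorescence values with its physical calibration.
#'
#' @param values Numeric matrix, rows = spatial pixels, columns = lines
#'   (time). Values must be finite and nonnegative.
#' @param pixel_size_um Spatial calibration (um/pixel).
#' @param line_rate_hz Temporal calibration (lines/s).
#' @return A `linescan` object.
#' @export
linescan <- function(values, pixel_size_um, line_rate_hz) {
  values <- as.matrix(values)
  if (!all(is.finite(values)) || any(values < 0)) {
    abort("line-scan values must be finite and nonnegative",
          class = "myospark_input_error")
  }
  if (pixel_size_um <= 0 || line_rate_hz <= 0) {
    abort("calibrations must be positive", class = "myospark_input_error")
  }
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 line_rate_hz = line_rate_hz), class = "linescan")
}

#' @export
print.linescan <- function(x, ...) {
  cat(sprintf("<linescan> %d px x %d lines (%.1f um x %.2f s; %.3f um/px, %g lines/s)\n",
              nrow(x$values), ncol(x$values),
              nrow(x$values) * x$pixel_size_um,
              ncol(x$values) / x$line_rate_hz,
              x$pixel_size_um, x$line_rate_hz))
  invisible(x)
}

#' @export
dim.linescan <- function(x) dim(x$values)

#' Write / read a line-scan as 32-bit TIFF plus a JSON sidecar
#'
#' The image is stored as a single-channel float TIFF with axis order
#' (space, time); calibration (and, when available, simulation ground truth)
#' travels in a sidecar JSON next to it.
#'
#' @param x A `linescan` or `linescan_sim` object.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_linescan()` returns `path` invisibly; `read_linescan()`
#'   returns a `linescan` (with a `truth` attribute if the sidecar carries
#'   one).
#' @export
write_linescan <- function(x, path) {
  sim_truth <- NULL
  cfg <- NULL
  if (inherits(x, "linescan_sim")) {
    sim_truth <- x$truth
    cfg <- x$config
    x <- x$image
  }
  stopifnot(inherits(x, "linescan"))
  # tiff::writeTIFF expects values in [0,1] unless writing floats natively
  tiff::writeTIFF(x$values / max(x$values), path, bits.per.sample = 32L,
                  reduce = TRUE)
  sidecar <- list(pixel_size_um = x$pixel_size_um,
                  line_rate_hz = x$line_rate_hz,
                  scale = max(x$values))
  if (!is.null(sim_truth)) sidecar$truth <- sim_truth
  if (!is.null(cfg)) sidecar$config <- unclass(cfg)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_linescan
#' @param pixel_size_um,line_rate_hz Calibration overrides used when no
#'   sidecar JSON is present.
#' @export
read_linescan <- function(path, pixel_size_um = NULL, line_rate_hz = NULL) {
  vals <- tiff::readTIFF(path, as.is = FALSE)
  if (is.list(vals)) vals <- vals[[1]]
  scale <- 1
  sidecar_path <- paste0(path, ".json")
  truth <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    pixel_size_um <- pixel_size_um %||% sc$pixel_size_um
    line_rate_hz <- line_rate_hz %||% sc$line_rate_hz
    scale <- sc$scale %||% 1
    if (!is.null(sc$truth)) truth <- as_tibble(sc$truth)
  }
  if (is.null(pixel_size_um) || is.null(line_rate_hz)) {
    abort("no sidecar JSON found; supply pixel_size_um and line_rate_hz",
          class = "myospark_input_error")
  }
  out <- linescan(vals * scale, pixel_size_um, line_rate_hz)
  if (!is.null(truth)) attr(out, "truth") <- truth
  out
}
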