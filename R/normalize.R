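#' Normalize a line-scan to dF/F0
#'
#' Computes the per-position baseline F0 as the median fluorescence of each
#' spatial position over a declared baseline window, or over event-free lines
#' (columns whose spatial mean lies at or below the median of all column
#' means) when no window is given, then forms dF/F0 = (F - F0)/F0.
#' Background noise statistics (mean and SD of the normalized image over
#' event-free pixels) are estimated robustly and drive threshold-based event
#' detection downstream.
#'
#' @param img A [linescan()].
#' @param baseline_window Optional integer vector `c(first, last)` of time
#'   (column) indices used for F0.
#' @return A `normalized_linescan`: `dff0` matrix, `f0_profile`,
#'   `background_mean`, `background_sd`, logical `analyzed_mask`, and the
#'   calibrations.
#' @export
normalize_linescan <- function(img, baseline_window = NULL) {
  stopifnot(inherits(img, "linescan"))
  v <- img$values
  if (length(v) == 0) abort("empty image", class = "myospark_input_error")
  n_t <- ncol(v)
  if (is.null(baseline_window)) {
    col_means <- colMeans(v)
    base_cols <- which(col_means <= median(col_means))
  } else {
    if (baseline_window[1] < 1 || baseline_window[2] > n_t ||
        baseline_window[1] > baseline_window[2]) {
      abort("baseline_window outside time range",
            class = "myospark_input_error")
    }
    base_cols <- seq(baseline_window[1], baseline_window[2])
  }
  f0 <- apply(v[, base_cols, drop = FALSE], 1, median)
  if (any(f0 <= 0)) {
    abort(sprintf("nonpositive F0 at positions: %s",
                  paste(which(f0 <= 0), collapse = ", ")),
          class = "myospark_normalization_error")
  }
  dff0 <- sweep(sweep(v, 1, f0, "-"), 1, f0, "/")

  # event-free pixels: start from the quiet (baseline) columns, then trim
  # residual event pixels with one robust pass; release events are
  # positive, so the central band of the quiet columns is noise
  sub <- dff0[, base_cols, drop = FALSE]
  ctr <- median(sub)
  scl <- mad(sub)
  bg <- sub[abs(sub - ctr) <= 3 * max(scl, 1e-12)]
  structure(list(
    dff0 = dff0, f0_profile = f0,
    background_mean = mean(bg),
    background_sd = if (length(bg) > 1) sd(bg) else 0,
    analyzed_mask = matrix(TRUE, nrow(v), ncol(v)),
    pixel_size_um = img$pixel_size_um,
    line_rate_hz = img$line_rate_hz), class = "normalized_linescan")
}

#' @export
print.normalized_linescan <- function(x, ...) {
  cat(sprintf("<normalized_linescan> %d px x %d lines; bg %.4f +/- %.4f; %.0f%% analyzed\n",
              nrow(x$dff0), ncol(x$dff0), x$background_mean, x$background_sd,
              100 * mean(x$analyzed_mask)))
  invisible(x)
}

#' Exclude paced-transient regions from spark analysis
#'
#' Clears the analyzed mask over each whole-line transient interval, padded
#' by a margin on both sides, so spark detection and frequency normalization
#' only see diastolic portions of the recording.
#'
#' @param norm A `normalized_linescan`.
#' @param transient_times Two-column matrix or list of `c(start_s, end_s)`
#'   intervals.
#' @param margin_ms Padding applied to each side of every interval.
#' @return The `normalized_linescan` with an updated `analyzed_mask`.
#' @export
exclude_transient_regions <- function(norm, transient_times, margin_ms = 50) {
  stopifnot(inherits(norm, "normalized_linescan"))
  if (is.list(transient_times)) {
    transient_times <- do.call(rbind, transient_times)
  }
  if (is.null(transient_times) || length(transient_times) == 0) return(norm)
  transient_times <- matrix(transient_times, ncol = 2)
  n_t <- ncol(norm$dff0)
  t_of <- function(j) (j - 1) / norm$line_rate_hz
  tt <- t_of(seq_len(n_t))
  for (i in seq_len(nrow(transient_times))) {
    lo <- transient_times[i, 1] - margin_ms / 1000
    hi <- transient_times[i, 2] + margin_ms / 1000
    norm$analyzed_mask[, tt >= lo & tt <= hi] <- FALSE
  }
  norm
}

#' Analyzed (unmasked) duration of a normalized line-scan, in seconds
#' @param norm A `normalized_linescan`.
#' @export
analyzed_duration_s <- function(norm) {
  stopifnot(inherits(norm, "normalized_linescan"))
  sum(colSums(norm$analyzed_mask) > 0) / norm$line_rate_hz
}
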