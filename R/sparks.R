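#' Spark detection configuration
#'
#' @param criteria Detection multiplier: events must exceed
#'   `background_mean + criteria * background_sd` on the smoothed normalized
#'   image. The conventional value for line-scan spark detection is 3.8.
#' @param min_area_px Minimum supra-threshold connected area (pixels).
#' @param merge_gap_px Chebyshev gap (pixels) closed before labeling, so
#'   fragments of one event separated by at most this many sub-threshold
#'   pixels merge.
#' @return A `spark_detection_config` list.
#' @export
spark_detection_config <- function(criteria = 3.8, min_area_px = 4,
                                   merge_gap_px = 1) {
  if (criteria <= 0) abort("criteria must be positive",
                           class = "myospark_config_error")
  if (min_area_px < 1) abort("min_area_px must be >= 1",
                             class = "myospark_config_error")
  if (merge_gap_px < 0) abort("merge_gap_px must be >= 0",
                              class = "myospark_config_error")
  structure(list(criteria = criteria, min_area_px = min_area_px,
                 merge_gap_px = merge_gap_px),
            class = "spark_detection_config")
}

# 3x3 boxcar mean with in-bounds normalization (edges average fewer pixels).
boxcar3 <- function(m) {
  n_r <- nrow(m); n_c <- ncol(m)
  acc <- matrix(0, n_r, n_c)
  cnt <- matrix(0, n_r, n_c)
  for (di in -1:1) for (dj in -1:1) {
    ri <- max(1, 1 + di):min(n_r, n_r + di)
    rj <- max(1, 1 + dj):min(n_c, n_c + dj)
    si <- ri - di; sj <- rj - dj
    acc[ri, rj] <- acc[ri, rj] + m[si, sj, drop = FALSE]
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  acc / cnt
}

#' Detect calcium spark candidates on a normalized line-scan
#'
#' The normalized image is smoothed with a 3x3 boxcar and thresholded at
#' `background_mean + criteria * background_sd`.  Supra-threshold pixels
#' inside the analyzed mask are dilated by `merge_gap_px` (square
#' neighborhood), connected components are labeled with 8-connectivity on
#' the dilated set, labels are mapped back to the original supra-threshold
#' pixels, and components smaller than `min_area_px` are dropped.  One
#' candidate is emitted per component, at the maximum of the smoothed image
#' within it.
#'
#' @param norm A `normalized_linescan`.
#' @param cfg A [spark_detection_config()].
#' @return Tibble of candidates: `label`, `peak_i` (space index), `peak_j`
#'   (time index), `area_px`, `peak_smoothed`.
#' @export
detect_sparks <- function(norm, cfg = spark_detection_config()) {
  stopifnot(inherits(norm, "normalized_linescan"),
            inherits(cfg, "spark_detection_config"))
  empty <- tibble(label = integer(), peak_i = integer(), peak_j = integer(),
                  area_px = integer(), peak_smoothed = numeric())
  if (!any(norm$analyzed_mask)) {
    warn("entire image is masked; no spark detection performed")
    return(empty)
  }
  if (norm$background_sd <= 0) {
    abort("background_sd must be positive for threshold detection",
          class = "myospark_input_error")
  }
  sm <- boxcar3(norm$dff0)
  thr <- norm$background_mean + cfg$criteria * norm$background_sd
  binary <- (sm > thr) & norm$analyzed_mask
  if (!any(binary)) return(empty)

  work <- binary
  if (cfg$merge_gap_px > 0) {
    brush <- EBImage::makeBrush(2 * cfg$merge_gap_px + 1, shape = "box")
    work <- EBImage::dilate(EBImage::Image(binary * 1), brush) > 0
  }
  lab <- EBImage::bwlabel(EBImage::Image(work * 1))
  lab <- matrix(as.integer(lab), nrow(binary), ncol(binary))
  lab[!binary] <- 0L

  keep <- which(tabulate(lab[lab > 0L]) >= cfg$min_area_px)
  if (length(keep) == 0) return(empty)
  out <- lapply(keep, function(lb) {
    idx <- which(lab == lb)
    pk <- idx[which.max(sm[idx])]
    tibble(label = lb,
           peak_i = ((pk - 1L) %% nrow(sm)) + 1L,
           peak_j = ((pk - 1L) %/% nrow(sm)) + 1L,
           area_px = length(idx),
           peak_smoothed = sm[pk])
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$peak_j, .data$peak_i)
}

# 3-point running median despike.  Exact identity on monotone profiles, so
# it cannot bias half-maximum crossings of a clean kernel; it only removes
# isolated noise dips that would otherwise trigger spuriously early
# crossings on the raw profile.
despike3 <- function(v) {
  if (length(v) < 3) return(v)
  as.numeric(stats::runmed(v, 3))
}

# First sustained half-maximum crossing on each side of a peak, by linear
# interpolation; the profile must stay on the far side of the half level for
# `sustain` samples, so a brief noise excursion does not register as the
# event's crossing (on a clean monotone flank the sustained crossing is the
# plain crossing).  NA when the half level is never crossed inside the
# profile (truncated event).  Returns crossing coordinates in index units.
half_max_crossings <- function(profile, peak_idx, half, sustain = 3) {
  n <- length(profile)
  left <- NA_real_
  if (peak_idx > 1) for (i in seq(peak_idx, 2)) {
    if (profile[i - 1] < half && profile[i] >= half &&
        all(profile[max(1, i - sustain):(i - 1)] < half)) {
      left <- (i - 1) + (half - profile[i - 1]) / (profile[i] - profile[i - 1])
      break
    }
  }
  right <- NA_real_
  if (peak_idx < n) {
    for (i in seq(peak_idx, n - 1)) {
      if (profile[i] >= half && profile[i + 1] < half &&
          all(profile[(i + 1):min(n, i + sustain)] < half)) {
        right <- i + (profile[i] - half) / (profile[i] - profile[i + 1])
        break
      }
    }
  }
  c(left = left, right = right)
}

#' Measure one spark candidate
#'
#' Amplitude is the unsmoothed dF/F0 at the candidate peak; FWHM is measured
#' on the spatial profile through the peak time and FDHM on the temporal
#' profile through the peak position, each as the distance between the two
#' half-maximum crossings (half level halfway between the background mean
#' and the peak) located by linear interpolation, converted to um and ms.
#' Profiles are despiked with a 3-point running median first -- an exact
#' identity on monotone profiles -- and a crossing must be sustained for
#' three samples, so isolated noise dips do not trigger spuriously early
#' crossings; the profile values themselves stay unsmoothed.
#' Events whose half level is not bracketed inside the image are flagged
#' `truncated` and carry NA width/duration.
#'
#' @param norm A `normalized_linescan`.
#' @param candidate One row of the [detect_sparks()] output.
#' @return One-row tibble: `peak_position_um`, `peak_time_ms`, `amplitude`,
#'   `fwhm_um`, `fdhm_ms`, `truncated`.
#' @export
measure_spark <- function(norm, candidate) {
  stopifnot(inherits(norm, "normalized_linescan"))
  i <- candidate$peak_i[1]; j <- candidate$peak_j[1]
  amp <- norm$dff0[i, j]
  base <- norm$background_mean
  half <- base + (amp - base) / 2

  sp <- half_max_crossings(despike3(norm$dff0[, j]), i, half)
  tp <- half_max_crossings(despike3(norm$dff0[i, ]), j, half)
  truncated <- any(is.na(sp)) || any(is.na(tp))
  tibble(
    peak_position_um = (i - 0.5) * norm$pixel_size_um,
    peak_time_ms = (j - 1) / norm$line_rate_hz * 1000,
    amplitude = amp,
    fwhm_um = if (truncated) NA_real_ else
      unname(diff(sp)) * norm$pixel_size_um,
    fdhm_ms = if (truncated) NA_real_ else
      unname(diff(tp)) / norm$line_rate_hz * 1000,
    truncated = truncated)
}

#' Detect and measure all sparks in a normalized line-scan
#'
#' @inheritParams detect_sparks
#' @return Tibble of measured spark events (see [measure_spark()]).
#' @export
measure_sparks <- function(norm, cfg = spark_detection_config()) {
  cands <- detect_sparks(norm, cfg)
  if (nrow(cands) == 0) {
    return(tibble(peak_position_um = numeric(), peak_time_ms = numeric(),
                  amplitude = numeric(), fwhm_um = numeric(),
                  fdhm_ms = numeric(), truncated = logical()))
  }
  purrr::map_dfr(seq_len(nrow(cands)),
                 function(k) measure_spark(norm, cands[k, ]))
}

#' Spark frequency in events per 100 um per second
#'
#' @param events Tibble of spark events.
#' @param norm The `normalized_linescan` they came from (provides the scan
#'   length and the analyzed, i.e. unmasked, duration).
#' @return Frequency (events / 100 um / s); `NA` when no analyzable time
#'   remains.
#' @export
spark_frequency <- function(events, norm) {
  dur <- analyzed_duration_s(norm)
  if (dur <= 0) {
    warn("zero analyzable duration; spark frequency undefined")
    return(NA_real_)
  }
  scan_um <- nrow(norm$dff0) * norm$pixel_size_um
  nrow(events) / (scan_um / 100) / dur
}

#' Summarize spark morphometry with kernel density estimates
#'
#' Per-parameter Gaussian kernel density estimates (Silverman's
#' rule-of-thumb bandwidth, grid spanning the data range plus three
#' bandwidths) together with count, frequency, means and SDs.  Truncated
#' events contribute to amplitude and count but are excluded from
#' width/duration statistics.
#'
#' @param events Tibble of spark events.
#' @param norm The source `normalized_linescan`.
#' @return A `spark_summary` object with `stats` (tibble) and `kde` (named
#'   list of tibbles `x`, `density`).
#' @export
summarize_sparks <- function(events, norm) {
  ok <- events[!events$truncated, , drop = FALSE]
  params <- list(amplitude = events$amplitude,
                 fwhm_um = ok$fwhm_um, fdhm_ms = ok$fdhm_ms)
  kde <- purrr::map(params, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 1) return(NULL)
    d <- if (length(v) == 1 || sd(v) == 0) {
      bw <- max(abs(v[1]) * 0.05, 0.01)
      density(v, bw = bw, cut = 3)
    } else density(v, bw = "nrd0", cut = 3)
    tibble(x = d$x, density = d$y)
  })
  kde <- kde[!purrr::map_lgl(kde, is.null)]
  stats <- tibble(
    n_events = nrow(events),
    frequency_per_100um_s = spark_frequency(events, norm),
    amplitude_mean = mean(events$amplitude),
    amplitude_sd = sd(events$amplitude),
    fwhm_um_mean = mean(ok$fwhm_um),
    fwhm_um_sd = sd(ok$fwhm_um),
    fdhm_ms_mean = mean(ok$fdhm_ms),
    fdhm_ms_sd = sd(ok$fdhm_ms))
  structure(list(stats = stats, kde = kde, events = events),
            class = "spark_summary")
}

#' @export
print.spark_summary <- function(x, ...) {
  cat(sprintf("<spark_summary> %d events, %.3f /100um/s\n",
              x$stats$n_events, x$stats$frequency_per_100um_s))
  invisible(x)
}

#' @rdname summarize_sparks
#' @param x A `spark_summary`.
#' @param ... Unused.
#' @method tidy spark_summary
#' @export
tidy.spark_summary <- function(x, ...) {
  tidyr::pivot_longer(x$stats, dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' @rdname summarize_sparks
#' @method glance spark_summary
#' @export
glance.spark_summary <- function(x, ...) x$stats

#' Linear dependence of spark duration on amplitude
#'
#' Coefficient of determination of the ordinary least-squares regression of
#' FDHM on amplitude; a weak r-squared indicates prolonged events are not
#' merely large ones.
#'
#' @param events Tibble of spark events (at least 3 non-truncated).
#' @return r-squared, or `NA` when amplitude has zero variance.
#' @export
fdhm_amplitude_r2 <- function(events) {
  ok <- events[!events$truncated & is.finite(events$fdhm_ms), , drop = FALSE]
  if (nrow(ok) < 3) abort("need at least 3 measurable events",
                          class = "myospark_input_error")
  if (sd(ok$amplitude) == 0) {
    warn("zero amplitude variance; r-squared undefined")
    return(NA_real_)
  }
  summary(lm(fdhm_ms ~ amplitude, data = ok))$r.squared
}
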