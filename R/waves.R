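#' Segment whole-line calcium transients on a normalized line-scan
#'
#' The spatially averaged dF/F0 trace is scanned for prominent peaks; peaks
#' exceeding a fraction of the largest whole-line amplitude (and a robust
#' noise floor) become transients.  Each transient interval runs from the
#' rising 20%-amplitude crossing to the falling 20%-amplitude crossing;
#' diastolic intervals are the complement with a margin.
#'
#' @param norm A `normalized_linescan`.
#' @param peak_fraction Minimum peak height as a fraction of the maximum
#'   whole-line amplitude.
#' @param min_amplitude Absolute floor (dF/F0) on the spatially averaged
#'   peak; keeps sparks and noise in quiescent scans from being read as
#'   whole-line transients.
#' @param min_separation_ms Minimum peak separation (ms).
#' @param margin_ms Margin trimmed from each side of the diastolic
#'   complement.
#' @return A `transient_segmentation`: `transients` tibble (`onset_s`,
#'   `peak_s`, `end_s`, `amplitude`, `beat_period_s`), `diastolic_intervals`
#'   tibble (`start_s`, `end_s`), and `duration_s`.
#' @export
segment_transients <- function(norm, peak_fraction = 0.3,
                               min_amplitude = 0.3,
                               min_separation_ms = 200, margin_ms = 50,
                               sync_tol_ms = 10) {
  stopifnot(inherits(norm, "normalized_linescan"))
  trace <- colMeans(norm$dff0)
  fs <- norm$line_rate_hz
  n <- length(trace)
  duration <- n / fs
  height <- max(peak_fraction * max(trace), min_amplitude)
  pk <- pracma::findpeaks(zero = "+", trace, minpeakheight = height,
                          minpeakdistance = max(2, round(min_separation_ms / 1000 * fs)))
  empty_tr <- tibble(onset_s = numeric(), peak_s = numeric(),
                     end_s = numeric(), amplitude = numeric(),
                     beat_period_s = numeric())
  if (is.null(pk)) {
    return(structure(list(transients = empty_tr,
                          diastolic_intervals = tibble(start_s = 0,
                                                       end_s = duration),
                          duration_s = duration),
                     class = "transient_segmentation"))
  }
  idx <- pk[, 2]; amp <- pk[, 1]
  bounds_of <- function(k) {
    # run out to the 5% crossing so the decay tail (which can stay above
    # the wave-detection threshold) is not counted as diastole
    lvl <- 0.05 * amp[k]
    i0 <- idx[k]
    while (i0 > 1 && trace[i0 - 1] > lvl) i0 <- i0 - 1
    i1 <- idx[k]
    while (i1 < n && trace[i1 + 1] > lvl) i1 <- i1 + 1
    c(i0, i1)
  }
  # one peak per transient: take peaks in descending amplitude and drop
  # any that fall inside an already-accepted transient's interval
  # (sparks or noise riding a transient's decay are not separate beats)
  keep <- integer(0); kept_bounds <- list()
  for (k in order(amp, decreasing = TRUE)) {
    inside <- any(vapply(kept_bounds, function(b)
      idx[k] >= b[1] && idx[k] <= b[2], logical(1)))
    if (inside) next
    keep <- c(keep, k)
    kept_bounds[[length(kept_bounds) + 1L]] <- bounds_of(k)
  }
  ord <- order(idx[keep])
  bounds <- kept_bounds[ord]
  idx <- idx[keep][ord]; amp <- amp[keep][ord]

  # whole-line transients are spatially synchronous: every position crosses
  # half-maximum within the rise time.  A propagating wave reaches positions
  # sequentially, so its half-max crossing times are dispersed.  Peaks whose
  # crossing-time SD exceeds the tolerance are wave candidates, not beats;
  # they are dropped here and their interval stays diastolic so wave
  # detection can see them.
  sync_ms <- vapply(seq_along(idx), function(k) {
    b <- bounds[[k]]; cols <- b[1]:b[2]
    subm <- norm$dff0[, cols, drop = FALSE]
    rmax <- apply(subm, 1, max)
    rows <- which(rmax >= 0.5 * amp[k])
    if (length(rows) < 2) return(Inf)
    cross <- vapply(rows, function(r)
      which(subm[r, ] >= 0.5 * rmax[r])[1], numeric(1))
    sd(cross) / fs * 1000
  }, numeric(1))
  sync <- sync_ms <= sync_tol_ms
  bounds <- bounds[sync]; idx <- idx[sync]; amp <- amp[sync]
  if (length(idx) == 0) {
    return(structure(list(transients = empty_tr,
                          diastolic_intervals = tibble(start_s = 0,
                                                       end_s = duration),
                          duration_s = duration),
                     class = "transient_segmentation"))
  }
  onset <- vapply(bounds, `[`, numeric(1), 1) / fs
  endt <- vapply(bounds, `[`, numeric(1), 2) / fs
  transients <- tibble(
    onset_s = onset, peak_s = (idx - 1) / fs, end_s = endt,
    amplitude = amp,
    beat_period_s = c(diff(onset), NA_real_))

  m <- margin_ms / 1000
  dia <- list()
  cursor <- 0
  for (k in seq_along(onset)) {
    lo <- cursor; hi <- onset[k] - m
    if (hi - lo > 2 * m) dia[[length(dia) + 1L]] <- c(lo, hi)
    cursor <- endt[k] + m
  }
  if (duration - cursor > 2 * m) dia[[length(dia) + 1L]] <- c(cursor, duration)
  dia <- if (length(dia)) {
    d <- do.call(rbind, dia)
    tibble(start_s = d[, 1], end_s = d[, 2])
  } else tibble(start_s = numeric(), end_s = numeric())

  structure(list(transients = transients, diastolic_intervals = dia,
                 duration_s = duration),
            class = "transient_segmentation")
}

#' @export
print.transient_segmentation <- function(x, ...) {
  cat(sprintf("<transient_segmentation> %d transient(s), %d diastolic interval(s) over %.2f s\n",
              nrow(x$transients), nrow(x$diastolic_intervals), x$duration_s))
  invisible(x)
}

#' Detect spontaneous diastolic calcium waves and wavelets
#'
#' Within diastolic intervals, supra-threshold connected regions of the
#' smoothed normalized image whose spatial extent exceeds a minimum fraction
#' of the scan length become wave events; events reaching the whole-cell
#' threshold are waves, smaller ones wavelets.  Regions below the minimum
#' extent are left to spark analysis.
#'
#' @param norm A `normalized_linescan`.
#' @param seg A `transient_segmentation` for the same scan.
#' @param wave_criteria Threshold multiplier on the background SD.
#' @param min_extent_fraction Minimum spatial extent (fraction of scan
#'   length) for a region to count as a wave event.
#' @param whole_cell_fraction Extent at or above which the event is a
#'   whole-cell wave rather than a wavelet.
#' @return Tibble of wave events: `onset_s`, `amplitude`,
#'   `extent_fraction`, `kind`.
#' @export
detect_waves <- function(norm, seg, wave_criteria = 3.8,
                         min_extent_fraction = 0.2,
                         whole_cell_fraction = 0.9) {
  stopifnot(inherits(norm, "normalized_linescan"),
            inherits(seg, "transient_segmentation"))
  empty <- tibble(onset_s = numeric(), amplitude = numeric(),
                  extent_fraction = numeric(), kind = character())
  if (nrow(seg$diastolic_intervals) == 0) return(empty)
  fs <- norm$line_rate_hz
  n_x <- nrow(norm$dff0); n_t <- ncol(norm$dff0)
  tt <- (seq_len(n_t) - 1) / fs
  dia_cols <- rep(FALSE, n_t)
  for (k in seq_len(nrow(seg$diastolic_intervals))) {
    dia_cols <- dia_cols | (tt >= seg$diastolic_intervals$start_s[k] &
                              tt < seg$diastolic_intervals$end_s[k])
  }
  sm <- boxcar3(norm$dff0)
  thr <- norm$background_mean + wave_criteria * norm$background_sd
  binary <- sm > thr
  binary[, !dia_cols] <- FALSE
  if (!any(binary)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(binary * 1))
  lab <- matrix(as.integer(lab), n_x, n_t)
  out <- list()
  for (lb in seq_len(max(lab))) {
    idx <- which(lab == lb, arr.ind = TRUE)
    extent <- (max(idx[, 1]) - min(idx[, 1]) + 1) / n_x
    if (extent < min_extent_fraction) next
    vals <- norm$dff0[lab == lb]
    out[[length(out) + 1L]] <- tibble(
      onset_s = (min(idx[, 2]) - 1) / fs,
      amplitude = max(vals),
      extent_fraction = extent,
      kind = if (extent >= whole_cell_fraction) "wave" else "wavelet")
  }
  if (!length(out)) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$onset_s)
}

#' Classify one line-scan as normal, SCW, or other
#'
#' Precedence: any detected wave or wavelet makes the scan SCW; otherwise
#' irregular transients (amplitude or beat-period coefficient of variation
#' above tolerance, or fewer than two beats) make it `other`; otherwise it
#' is `normal`.
#'
#' @param seg A `transient_segmentation`.
#' @param waves Output of [detect_waves()] for the same scan.
#' @param amp_cv_tol,bp_cv_tol Coefficient-of-variation tolerances
#'   (fractions) on transient amplitude and beat period.
#' @return A `scan_classification`: `label` plus an `evidence` tibble
#'   (wave count, amplitude CV, beat-period CV, reason).
#' @export
classify_linescan <- function(seg, waves, amp_cv_tol = 0.25,
                              bp_cv_tol = 0.25) {
  stopifnot(inherits(seg, "transient_segmentation"))
  n_tr <- nrow(seg$transients)
  amp_cv <- if (n_tr >= 2) sd(seg$transients$amplitude) /
    mean(seg$transients$amplitude) else NA_real_
  bp <- seg$transients$beat_period_s
  bp <- bp[is.finite(bp)]
  bp_cv <- if (length(bp) >= 2) sd(bp) / mean(bp) else NA_real_

  if (nrow(waves) >= 1) {
    label <- "scw"; reason <- "spontaneous wave(s) detected"
  } else if (n_tr < 2) {
    label <- "other"; reason <- "insufficient beats"
  } else if (is.finite(amp_cv) && amp_cv > amp_cv_tol) {
    label <- "other"; reason <- "amplitude variability above tolerance"
  } else if (is.finite(bp_cv) && bp_cv > bp_cv_tol) {
    label <- "other"; reason <- "beat-period variability above tolerance"
  } else {
    label <- "normal"; reason <- "consistent amplitudes and beat periods"
  }
  structure(list(
    label = label,
    evidence = tibble(n_waves = nrow(waves), n_transients = n_tr,
                      amplitude_cv = amp_cv, beat_period_cv = bp_cv,
                      reason = reason)),
    class = "scan_classification")
}

#' @export
print.scan_classification <- function(x, ...) {
  cat(sprintf("<scan_classification> %s (%s)\n", x$label,
              x$evidence$reason))
  invisible(x)
}

#' Per-cell wave amplitude and frequency
#'
#' @param waves Tibble of wave events.
#' @param diastolic_duration_s Total analyzed diastolic duration (s).
#' @return One-row tibble `n_waves`, `mean_amplitude`, `frequency_per_s`;
#'   amplitude and frequency are `NA` (missing, not zero) when no waves
#'   were detected.
#' @export
wave_stats <- function(waves, diastolic_duration_s) {
  if (diastolic_duration_s <= 0) {
    abort("diastolic duration must be positive",
          class = "myospark_input_error")
  }
  if (nrow(waves) == 0) {
    return(tibble(n_waves = 0L, mean_amplitude = NA_real_,
                  frequency_per_s = NA_real_))
  }
  tibble(n_waves = nrow(waves),
         mean_amplitude = mean(waves$amplitude),
         frequency_per_s = nrow(waves) / diastolic_duration_s)
}

#' Classify a simulated or recorded line-scan end to end
#'
#' Convenience wrapper: normalize, segment transients, mask them, detect
#' waves, classify.
#'
#' @param img A [linescan()].
#' @param ... Passed to [classify_linescan()].
#' @return The `scan_classification`, with the segmentation and waves
#'   attached as attributes.
#' @export
classify_scan <- function(img, ...) {
  norm <- normalize_linescan(img)
  seg <- segment_transients(norm)
  waves <- detect_waves(norm, seg)
  cls <- classify_linescan(seg, waves, ...)
  attr(cls, "segmentation") <- seg
  attr(cls, "waves") <- waves
  cls
}
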