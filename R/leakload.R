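#' Segment a leak/load protocol trace into phases
#'
#' With annotations (the primary path) the supplied switch times are turned
#' into ordered phase intervals.  Without annotations a fallback detector
#' locates the protocol landmarks from the trace itself: the end of pacing
#' from the regular paced peaks, the tetracaine onset from the sustained
#' negative deflection, the caffeine onset from the rise to the global
#' post-drop maximum, and the recovery onset from the sustained positive
#' derivative after the caffeine transient.
#'
#' @param trace Tibble with `time_s` (strictly increasing) and `value`
#'   (positive fluorescence).
#' @param annotations Optional named list/vector of switch times
#'   (`zero_na_ca_start`, `tetracaine_start`, `caffeine_start`,
#'   `recovery_start`), or a ready-made phase tibble as produced by
#'   [simulate_leakload_trace()].
#' @return Tibble `phase`, `start_s`, `end_s` for phases `paced_nt`,
#'   `zero_na_ca`, `tetracaine`, `caffeine`, `recovery_nt`.
#' @export
segment_phases <- function(trace, annotations = NULL) {
  check_trace(trace)
  t0 <- trace$time_s[1]
  t_end <- trace$time_s[nrow(trace)]
  if (is.data.frame(annotations)) {
    stopifnot(all(c("phase", "start_s", "end_s") %in% names(annotations)))
    return(as_tibble(annotations))
  }
  if (!is.null(annotations)) {
    a <- unlist(annotations)
    need <- c("zero_na_ca_start", "tetracaine_start", "caffeine_start",
              "recovery_start")
    if (!all(need %in% names(a))) {
      abort(paste("annotations must name:", paste(need, collapse = ", ")),
            class = "myospark_input_error")
    }
    a <- a[need]
    if (is.unsorted(a, strictly = TRUE)) {
      abort("annotation times out of protocol order",
            class = "myospark_input_error")
    }
    if (a[1] < t0 || a[length(a)] > t_end) {
      abort("annotation times outside the trace",
            class = "myospark_input_error")
    }
    return(tibble(
      phase = c("paced_nt", "zero_na_ca", "tetracaine", "caffeine",
                "recovery_nt"),
      start_s = c(t0, unname(a)),
      end_s = c(unname(a), t_end)))
  }

  ## fallback landmark detection
  fs <- 1 / median(diff(trace$time_s))
  v <- as.numeric(stats::runmed(trace$value, 1 + 2 * floor(0.05 * fs)))
  tt <- trace$time_s

  # paced peaks: prominent maxima in the first part of the recording
  pk <- pracma::findpeaks(zero = "+", v, minpeakdistance = max(2, round(0.3 * fs)),
                          minpeakheight = min(v) + 0.25 * (max(v) - min(v)))
  if (is.null(pk) || nrow(pk) < 3) {
    abort("fallback segmentation failed: no paced peaks found",
          class = "myospark_segmentation_error")
  }
  pk_t <- sort(tt[pk[, 2]])
  # drop the caffeine peak (global maximum) from the pacing train
  main_peak_t <- tt[which.max(v)]
  pace_t <- pk_t[pk_t < main_peak_t - 1]
  period <- median(diff(pace_t))
  # pacing started one beat-offset before the first peak; it ends one
  # period after the last paced peak minus that offset
  zero_start <- tail(pace_t, 1) + period - (pace_t[1] - t0)

  t_peak <- main_peak_t
  pre <- v[tt > zero_start & tt < t_peak]
  f_min <- min(pre)
  # caffeine onset: last time before the global peak near the leak floor
  lvl_c <- f_min + 0.02 * (max(v) - f_min)
  caff_start <- max(tt[tt < t_peak & tt > zero_start & v <= lvl_c])
  # tetracaine onset: last time before the floor at the pre-drop plateau
  f0_pre <- median(v[tt > zero_start & tt < zero_start + 1])
  lvl_t <- f0_pre - 0.05 * (f0_pre - f_min)
  tet_start <- max(tt[tt < caff_start & tt > zero_start & v >= lvl_t])
  # recovery onset: sustained positive derivative after the caffeine decay
  after <- which(tt > t_peak + 0.5)
  dv <- diff(v)
  win <- max(3, round(0.3 * fs))
  rec_start <- t_end
  run <- 0
  for (i in after[after < length(dv)]) {
    run <- if (dv[i] > 0) run + 1 else 0
    if (run >= win) { rec_start <- tt[i - win + 1]; break }
  }
  tibble(
    phase = c("paced_nt", "zero_na_ca", "tetracaine", "caffeine",
              "recovery_nt"),
    start_s = c(t0, zero_start, tet_start, caff_start, rec_start),
    end_s = c(zero_start, tet_start, caff_start, rec_start, t_end))
}

check_trace <- function(trace) {
  if (!all(c("time_s", "value") %in% names(trace))) {
    abort("trace needs columns time_s and value",
          class = "myospark_input_error")
  }
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    abort("time_s must be strictly increasing",
          class = "myospark_input_error")
  }
  if (!all(is.finite(trace$value)) || any(trace$value <= 0)) {
    abort("trace values must be finite and positive",
          class = "myospark_input_error")
  }
  invisible(trace)
}

phase_window <- function(seg, phase) {
  row <- seg[seg$phase == phase, ]
  if (nrow(row) != 1) {
    abort(sprintf("phase '%s' missing from segmentation", phase),
          class = "myospark_input_error")
  }
  c(row$start_s, row$end_s)
}

slice_phase <- function(trace, seg, phase) {
  w <- phase_window(seg, phase)
  trace[trace$time_s >= w[1] & trace$time_s < w[2], ]
}

#' Paced calcium transient amplitude, dF_trans / F0_diastolic
#'
#' The diastolic baseline is the mean of the per-beat diastolic minima over
#' the last `n_beats` steady-state beats; the systolic level is the mean of
#' the corresponding per-beat peaks; the amplitude is their normalized
#' difference.
#'
#' @param trace,seg Trace tibble and its [segment_phases()] output.
#' @param n_beats Number of terminal steady-state beats averaged.
#' @return List with `transient_amplitude`, `f0_diastolic`, `n_beats_found`.
#' @export
transient_amplitude <- function(trace, seg, n_beats = 5) {
  ph <- slice_phase(trace, seg, "paced_nt")
  fs <- 1 / median(diff(ph$time_s))
  v <- ph$value
  pk <- pracma::findpeaks(zero = "+", v, minpeakdistance = max(2, round(0.3 * fs)),
                          minpeakheight = min(v) + 0.5 * (max(v) - min(v)))
  if (is.null(pk) || nrow(pk) < n_beats) {
    abort("steady state not reached: fewer than 5 paced beats detected",
          class = "myospark_protocol_error")
  }
  ord <- order(pk[, 2])
  peak_idx <- pk[ord, 2]
  peak_val <- pk[ord, 1]
  n <- length(peak_idx)
  use <- seq(n - n_beats + 1, n)
  minima <- vapply(use, function(k) {
    lo <- peak_idx[k - 1]
    min(v[lo:peak_idx[k]])
  }, numeric(1))
  f0 <- mean(minima)
  peak <- mean(peak_val[use])
  list(transient_amplitude = (peak - f0) / f0, f0_diastolic = f0,
       n_beats_found = n)
}

#' Tetracaine-induced SR leak, dF_tet / F0_diastolic
#'
#' `dF_tet` is the difference between the diastolic fluorescence immediately
#' preceding tetracaine (the pre-drop 0 Na+/0 Ca2+ level) and the minimum
#' during the tetracaine phase (`F0_leak`).  A negative computed drop is
#' clamped to zero with a warning, since leak is physically nonnegative.
#'
#' @param trace,seg Trace and segmentation.
#' @param baseline_window_s Length of the pre-tetracaine window whose median
#'   defines the reference diastolic level.
#' @return List with `leak`, `f0_diastolic_pre`, `f0_leak`.
#' @export
sr_leak <- function(trace, seg, baseline_window_s = 1) {
  w <- phase_window(seg, "tetracaine")
  pre <- trace$value[trace$time_s >= w[1] - baseline_window_s &
                       trace$time_s < w[1]]
  if (length(pre) < 2) abort("no pre-tetracaine baseline available",
                             class = "myospark_protocol_error")
  f0_pre <- median(pre)
  tet <- slice_phase(trace, seg, "tetracaine")
  fs <- 1 / median(diff(tet$time_s))
  sm <- as.numeric(stats::runmed(tet$value, 1 + 2 * floor(0.05 * fs)))
  f_leak <- min(sm)
  leak <- (f0_pre - f_leak) / f0_pre
  if (leak < 0) {
    warn("tetracaine minimum above the pre-tetracaine baseline; leak clamped to 0")
    leak <- 0
    f_leak <- f0_pre
  }
  list(leak = leak, f0_diastolic_pre = f0_pre, f0_leak = f_leak)
}

#' Caffeine-induced SR load, dF_caff / F0_leak
#'
#' The caffeine peak is the global maximum of the caffeine interval;
#' `dF_caff` is its elevation above the tetracaine floor `F0_leak`.
#'
#' @param trace,seg Trace and segmentation.
#' @param f0_leak The tetracaine floor from [sr_leak()].
#' @return Load (dimensionless), 0 when the peak does not exceed the floor.
#' @export
sr_load <- function(trace, seg, f0_leak) {
  if (is.null(f0_leak) || !is.finite(f0_leak)) {
    abort("f0_leak unavailable: protocol order violated",
          class = "myospark_protocol_error")
  }
  caff <- slice_phase(trace, seg, "caffeine")
  max(0, (max(caff$value) - f0_leak) / f0_leak)
}

#' Fractional SR calcium release
#'
#' Ratio of the paced transient amplitude to the caffeine transient
#' amplitude; `NA` when the load is zero.
#'
#' @param transient_amplitude,load The two protocol statistics.
#' @return Dimensionless ratio or `NA`.
#' @export
fractional_release <- function(transient_amplitude, load) {
  if (!is.finite(load) || load <= 0) {
    warn("load is zero; fractional release undefined")
    return(NA_real_)
  }
  transient_amplitude / load
}

#' Detect spontaneous oscillations in the 0 Na+/0 Ca2+ window
#'
#' Peaks in the pre-tetracaine 0 Na+/0 Ca2+ interval exceeding
#' `baseline + k * noise SD` (robust estimates from the same window), with a
#' minimum separation.
#'
#' @param trace,seg Trace and segmentation.
#' @param k Threshold multiplier.
#' @param min_separation_s Minimum peak separation (s).
#' @return Tibble `time_s`, `amplitude` (dF/F0 above the window baseline).
#' @export
detect_oscillations <- function(trace, seg, k = 3.8, min_separation_s = 0.3) {
  ph <- slice_phase(trace, seg, "zero_na_ca")
  empty <- tibble(time_s = numeric(), amplitude = numeric())
  if (nrow(ph) < 5) return(empty)
  fs <- 1 / median(diff(ph$time_s))
  base <- median(ph$value)
  noise <- mad(ph$value)
  thr <- base + k * max(noise, 1e-9)
  pk <- pracma::findpeaks(zero = "+", ph$value, minpeakheight = thr,
                          minpeakdistance = max(2, round(min_separation_s * fs)))
  if (is.null(pk)) return(empty)
  tibble(time_s = ph$time_s[pk[, 2]],
         amplitude = (pk[, 1] - base) / base)
}

#' Run the full leak/load quantification on one trace
#'
#' @param trace Tibble `time_s`, `value`.
#' @param annotations Passed to [segment_phases()].
#' @param cell_id Identifier carried into the result.
#' @return A `leakload_result`: tibble-backed object with the four protocol
#'   statistics, the two baselines and the detected oscillations.
#' @export
analyze_leakload <- function(trace, annotations = NULL, cell_id = NA_character_) {
  check_trace(trace)
  seg <- segment_phases(trace, annotations)
  ta <- transient_amplitude(trace, seg)
  lk <- sr_leak(trace, seg)
  load <- sr_load(trace, seg, lk$f0_leak)
  fr <- fractional_release(ta$transient_amplitude, load)
  osc <- detect_oscillations(trace, seg)
  res <- tibble(cell_id = cell_id,
                transient_amplitude = ta$transient_amplitude,
                leak = lk$leak, load = load, fractional_release = fr,
                f0_diastolic = ta$f0_diastolic, f0_leak = lk$f0_leak,
                n_oscillations = nrow(osc))
  structure(list(result = res, oscillations = osc, segmentation = seg),
            class = "leakload_result")
}

#' @export
print.leakload_result <- function(x, ...) {
  r <- x$result
  cat(sprintf(paste0("<leakload_result> transient %.3f, leak %.3f, ",
                     "load %.3f, fractional release %.3f, %d oscillation(s)\n"),
              r$transient_amplitude, r$leak, r$load, r$fractional_release,
              r$n_oscillations))
  invisible(x)
}

#' @rdname analyze_leakload
#' @param x A `leakload_result`.
#' @param ... Unused.
#' @method tidy leakload_result
#' @export
tidy.leakload_result <- function(x, ...) {
  tidyr::pivot_longer(x$result, -dplyr::any_of("cell_id"),
                      names_to = "statistic", values_to = "value")
}

#' @rdname analyze_leakload
#' @method glance leakload_result
#' @export
glance.leakload_result <- function(x, ...) x$result
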