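#' Detect depolarization spikes in a field-potential trace
#'
#' Spikes are local extrema of |voltage| exceeding `k` times the robust
#' noise SD (median absolute deviation) and a relative amplitude floor
#' (`rel_threshold` of the largest deflection, which separates the sharp
#' depolarization spike from T-waves and afterdepolarizations), enforced
#' greedily by descending amplitude with a refractory period.
#'
#' @param trace Tibble `time_s`, `voltage_uv`.
#' @param k Threshold multiplier on the robust noise SD.
#' @param refractory_s Minimum spacing between spikes (s).
#' @param rel_threshold Amplitude floor as a fraction of the recording's
#'   largest |voltage|; deflections below it (repolarization waves, DADs)
#'   are never spikes.
#' @return Numeric vector of spike times (s), at the extremum sample.
#' @export
detect_spikes <- function(trace, k = 8, refractory_s = 0.2,
                          rel_threshold = 0.5) {
  check_fp_trace(trace)
  v <- abs(trace$voltage_uv)
  noise <- mad(trace$voltage_uv)
  thr <- max(k * max(noise, 1e-9), rel_threshold * max(v))
  cand <- which(v > thr)
  if (length(cand) == 0) {
    warn("no depolarization spikes detected")
    return(numeric(0))
  }
  cand <- cand[order(v[cand], decreasing = TRUE)]
  accepted <- numeric(0)
  for (i in cand) {
    ti <- trace$time_s[i]
    if (length(accepted) == 0 || all(abs(accepted - ti) >= refractory_s)) {
      accepted <- c(accepted, ti)
    }
  }
  sort(accepted)
}

check_fp_trace <- function(trace) {
  if (!all(c("time_s", "voltage_uv") %in% names(trace))) {
    abort("trace needs columns time_s and voltage_uv",
          class = "myospark_input_error")
  }
  if (!all(is.finite(trace$voltage_uv))) {
    abort("voltage must be finite", class = "myospark_input_error")
  }
  invisible(trace)
}

fp_sampling_hz <- function(trace) 1 / median(diff(trace$time_s))

smooth_ma <- function(v, w) {
  if (w <= 1) return(v)
  as.numeric(stats::filter(v, rep(1 / w, w), sides = 2)) |>
    (\(x) { x[is.na(x)] <- v[is.na(x)]; x })()
}

#' Measure field-potential duration (spike to T-wave) per beat
#'
#' For each spike, the T-wave is the largest smoothed deflection from the
#' local baseline in a search window from `search_start_ms` after the spike
#' to `search_frac` of the beat period; FPD is the spike-to-T-wave time in
#' milliseconds.  Beats whose window holds no deflection above the noise
#' floor are flagged and excluded from FPD summaries.
#'
#' @param trace Tibble `time_s`, `voltage_uv`.
#' @param spike_times Spike times from [detect_spikes()].
#' @param search_start_ms Start of the T-wave search window after the spike.
#' @param search_frac End of the window as a fraction of the beat period.
#' @param smooth_ms Moving-average smoothing window (ms).
#' @param min_snr Minimum T-wave deflection in units of smoothed noise SD.
#' @return Tibble `spike_time_s`, `twave_time_s`, `fpd_ms`, `flagged`.
#' @export
measure_fpd <- function(trace, spike_times, search_start_ms = 100,
                        search_frac = 0.8, smooth_ms = 5, min_snr = 4) {
  check_fp_trace(trace)
  if (length(spike_times) < 1) {
    abort("need at least one spike", class = "myospark_input_error")
  }
  fs <- fp_sampling_hz(trace)
  sm <- smooth_ma(trace$voltage_uv, max(1, round(smooth_ms / 1000 * fs)))
  bp_med <- if (length(spike_times) >= 2) median(diff(spike_times)) else
    (max(trace$time_s) - max(spike_times))
  noise <- mad(sm)
  out <- purrr::map_dfr(seq_along(spike_times), function(k) {
    s <- spike_times[k]
    bp <- if (k < length(spike_times)) spike_times[k + 1] - s else bp_med
    w0 <- s + search_start_ms / 1000
    w1 <- s + search_frac * bp
    idx <- which(trace$time_s >= w0 & trace$time_s <= w1)
    if (length(idx) < 3) {
      return(tibble(spike_time_s = s, twave_time_s = NA_real_,
                    fpd_ms = NA_real_, flagged = TRUE))
    }
    base <- median(sm[idx])
    defl <- abs(sm[idx] - base)
    pk <- idx[which.max(defl)]
    if (max(defl) < min_snr * max(noise, 1e-9)) {
      return(tibble(spike_time_s = s, twave_time_s = NA_real_,
                    fpd_ms = NA_real_, flagged = TRUE))
    }
    tibble(spike_time_s = s, twave_time_s = trace$time_s[pk],
           fpd_ms = (trace$time_s[pk] - s) * 1000, flagged = FALSE)
  })
  out
}

#' Fridericia rate correction of field-potential duration
#'
#' FPDcF = FPD / BP^(1/3) with the beat period in seconds, the standard
#' cube-root rate correction.
#'
#' @param fpd_ms Field-potential duration(s), ms.
#' @param bp_s Beat period(s), s; must be positive.
#' @param exponent Correction exponent (1/3 for Fridericia).
#' @return Corrected duration(s), ms.
#' @export
fridericia_correct <- function(fpd_ms, bp_s, exponent = 1 / 3) {
  if (any(bp_s[is.finite(bp_s)] <= 0)) {
    abort("beat period must be positive", class = "myospark_input_error")
  }
  fpd_ms / bp_s^exponent
}

#' Detect delayed afterdepolarizations in diastolic windows
#'
#' Within each diastolic window (T-wave plus margin to next spike minus
#' margin), the largest smoothed deflection from the window baseline is
#' scored against the spike amplitude; deflections inside the configured
#' amplitude band are DADs (larger ones are candidate ectopic spikes, not
#' DADs).
#'
#' @param trace Tibble `time_s`, `voltage_uv`.
#' @param beats Tibble from [measure_fpd()] (spike and T-wave times).
#' @param a_min,a_max DAD amplitude band as fractions of the spike
#'   amplitude.
#' @param margin_s Margin after the T-wave and before the next spike; the
#'   post-T-wave margin must clear the repolarization wave's tail so
#'   residual T-wave deflection is not read as a DAD.
#' @param smooth_ms Moving-average smoothing window (ms).
#' @return `beats` with added columns `dad` (flag), `dad_time_s`,
#'   `dad_score` (deflection / spike amplitude, for ROC analysis).
#' @export
detect_dads <- function(trace, beats, a_min = 0.05, a_max = 0.5,
                        margin_s = 0.1, smooth_ms = 5) {
  check_fp_trace(trace)
  fs <- fp_sampling_hz(trace)
  sm <- smooth_ma(trace$voltage_uv, max(1, round(smooth_ms / 1000 * fs)))
  spike_amp <- median(vapply(beats$spike_time_s, function(s) {
    idx <- which(abs(trace$time_s - s) <= 0.005)
    max(abs(trace$voltage_uv[idx]))
  }, numeric(1)))
  n <- nrow(beats)
  dad <- logical(n); dad_t <- rep(NA_real_, n); score <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (k == n || is.na(beats$twave_time_s[k])) next
    w0 <- beats$twave_time_s[k] + margin_s
    w1 <- beats$spike_time_s[k + 1] - margin_s
    idx <- which(trace$time_s >= w0 & trace$time_s <= w1)
    if (length(idx) < 3) next
    base <- median(sm[idx])
    defl <- abs(sm[idx] - base)
    pk <- which.max(defl)
    score[k] <- max(defl) / spike_amp
    if (score[k] >= a_min && score[k] <= a_max) {
      dad[k] <- TRUE
      dad_t[k] <- trace$time_s[idx[pk]]
    }
  }
  dplyr::mutate(beats, dad = dad, dad_time_s = dad_t, dad_score = score)
}

#' Poincare pairs of a beat-wise series
#'
#' @param series Numeric vector (e.g. beat periods or FPDcF in seconds).
#' @return Tibble `previous`, `current` with `length(series) - 1` rows.
#' @export
poincare_pairs <- function(series) {
  if (length(series) < 2) {
    abort("need at least 2 values for Poincare pairs",
          class = "myospark_input_error")
  }
  tibble(previous = series[-length(series)], current = series[-1])
}

#' Coefficient of variation, percent
#'
#' 100 times the sample standard deviation (n - 1 denominator) divided by
#' the mean.
#'
#' @param series Numeric vector.
#' @return Percent CV; `NA` when fewer than 2 finite values or zero mean.
#' @export
coefficient_of_variation <- function(series) {
  series <- series[is.finite(series)]
  if (length(series) < 2 || mean(series) == 0) {
    warn("coefficient of variation undefined")
    return(NA_real_)
  }
  100 * sd(series) / mean(series)
}

#' Annotate a field-potential recording end to end
#'
#' Runs spike detection, T-wave/FPD measurement, Fridericia correction
#' (each beat's FPD paired with the preceding inter-spike interval), DAD
#' detection, Poincare pairs, and coefficients of variation.
#'
#' @param trace Tibble `time_s`, `voltage_uv`.
#' @param spike_k,refractory_s Passed to [detect_spikes()].
#' @param ... Passed to [detect_dads()].
#' @return A `beat_series`: per-beat tibble `beats` (`spike_time_s`,
#'   `bp_s`, `twave_time_s`, `fpd_ms`, `fpdcf_ms`, `dad`, `dad_score`) and
#'   a one-row `summary` tibble (`n_beats`, `cv_bp_percent`,
#'   `cv_fpdcf_percent`, `dad_present`, `dad_count`), plus Poincare pair
#'   tables.
#' @export
analyze_field_potential <- function(trace, spike_k = 8, refractory_s = 0.2,
                                    ...) {
  spikes <- detect_spikes(trace, k = spike_k, refractory_s = refractory_s)
  if (length(spikes) < 2) {
    abort("fewer than 2 spikes; rhythm metrics unavailable",
          class = "myospark_input_error")
  }
  beats <- measure_fpd(trace, spikes)
  # BP terminating at beat k: interval from the previous spike
  beats$bp_s <- c(NA_real_, diff(spikes))
  beats$fpdcf_ms <- ifelse(is.finite(beats$bp_s),
                           fridericia_correct(beats$fpd_ms, beats$bp_s),
                           NA_real_)
  beats <- detect_dads(trace, beats, ...)
  bp <- beats$bp_s[is.finite(beats$bp_s)]
  fpdcf_s <- beats$fpdcf_ms[is.finite(beats$fpdcf_ms)] / 1000
  summary <- tibble(
    n_beats = nrow(beats),
    cv_bp_percent = coefficient_of_variation(bp),
    cv_fpdcf_percent = if (length(fpdcf_s) >= 2)
      coefficient_of_variation(fpdcf_s) else NA_real_,
    dad_present = any(beats$dad),
    dad_count = sum(beats$dad))
  structure(list(
    beats = beats, summary = summary,
    poincare_bp = poincare_pairs(bp),
    poincare_fpdcf = if (length(fpdcf_s) >= 2) poincare_pairs(fpdcf_s)
    else NULL), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<beat_series> %d beats; CV(BP) %.2f%%, CV(FPDcF) %.2f%%, %d DAD(s)\n",
              s$n_beats, s$cv_bp_percent, s$cv_fpdcf_percent, s$dad_count))
  invisible(x)
}

#' @rdname analyze_field_potential
#' @param x A `beat_series`.
#' @method tidy beat_series
#' @export
tidy.beat_series <- function(x, ...) x$beats

#' @rdname analyze_field_potential
#' @method glance beat_series
#' @export
glance.beat_series <- function(x, ...) x$summary
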