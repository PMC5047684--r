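#' Parameters for the field-potential (microelectrode array) simulator
#'
#' Emulates an extracellular recording of a spontaneously beating
#' cardiomyocyte aggregate: sharp biphasic depolarization spikes, a T-wave
#' after each spike at the field-potential duration, beat-period jitter at a
#' target coefficient of variation, optional delayed afterdepolarizations
#' (DADs) inserted after the T-wave of randomly flagged beats, and additive
#' noise.  Acquisition defaults mirror a 12.5 kHz MEA system.
#'
#' @param sampling_hz Sampling rate (Hz).
#' @param n_beats Number of beats rendered.
#' @param mean_bp_s Mean beat period (s).
#' @param bp_jitter_cv Target beat-period coefficient of variation (%).
#' @param fpd_ms_mean Field-potential duration: spike-to-T-wave time (ms).
#' @param fpd_jitter_cv Beat-to-beat FPD coefficient of variation (%).
#' @param spike_amplitude,twave_amplitude Template amplitudes (uV).
#' @param dad_probability Per-beat probability of inserting a DAD.
#' @param dad_amplitude_fraction DAD peak as a fraction of the spike
#'   amplitude, in (0, 1).
#' @param noise_sd Additive Gaussian noise SD (uV).
#' @param seed Integer seed.
#' @return A `fp_sim_params` list.
#' @export
fp_sim_params <- function(sampling_hz = 12500, n_beats = 60,
                          mean_bp_s = 1.0, bp_jitter_cv = 5,
                          fpd_ms_mean = 300, fpd_jitter_cv = 0,
                          spike_amplitude = 1000, twave_amplitude = 300,
                          dad_probability = 0, dad_amplitude_fraction = 0.2,
                          noise_sd = 10, seed = 1L) {
  p <- list(sampling_hz = sampling_hz, n_beats = as.integer(n_beats),
            mean_bp_s = mean_bp_s, bp_jitter_cv = bp_jitter_cv,
            fpd_ms_mean = fpd_ms_mean, fpd_jitter_cv = fpd_jitter_cv,
            spike_amplitude = spike_amplitude,
            twave_amplitude = twave_amplitude,
            dad_probability = dad_probability,
            dad_amplitude_fraction = dad_amplitude_fraction,
            noise_sd = noise_sd, seed = as.integer(seed))
  if (p$dad_amplitude_fraction <= 0 || p$dad_amplitude_fraction >= 1) {
    abort("dad_amplitude_fraction must lie in (0, 1)",
          class = "myospark_config_error")
  }
  if (p$mean_bp_s <= p$fpd_ms_mean / 1000) {
    abort("mean_bp_s must exceed the field-potential duration",
          class = "myospark_config_error")
  }
  if (p$n_beats < 2) abort("need at least 2 beats",
                           class = "myospark_config_error")
  if (p$dad_probability < 0 || p$dad_probability > 1) {
    abort("dad_probability must lie in [0, 1]",
          class = "myospark_config_error")
  }
  structure(p, class = "fp_sim_params")
}

gauss_bump <- function(t, center, sigma, amplitude) {
  amplitude * exp(-0.5 * ((t - center) / sigma)^2)
}

#' Simulate an extracellular field-potential trace with beat ground truth
#'
#' @param p A [fp_sim_params()].
#' @return A `fp_sim` list: `trace` (tibble `time_s`, `voltage_uv`),
#'   `truth` (per-beat tibble: `spike_time_s`, `twave_time_s`, `fpd_ms`,
#'   `dad`, `dad_time_s`), and `params`.
#' @export
simulate_field_potential <- function(p) {
  stopifnot(inherits(p, "fp_sim_params"))
  fs <- p$sampling_hz
  withr::with_seed(p$seed, {
    periods <- rnorm(p$n_beats - 1, p$mean_bp_s,
                     p$bp_jitter_cv / 100 * p$mean_bp_s)
    periods <- pmax(periods, 1.2 * p$fpd_ms_mean / 1000)
    spike_t <- 0.5 + c(0, cumsum(periods))
    spike_t <- round(spike_t * fs) / fs          # snap to the grid
    fpd <- rnorm(p$n_beats, p$fpd_ms_mean,
                 p$fpd_jitter_cv / 100 * p$fpd_ms_mean)
    fpd <- pmax(fpd, 50)
    twave_t <- round((spike_t + fpd / 1000) * fs) / fs
    dad <- runif(p$n_beats) < p$dad_probability
    dad[p$n_beats] <- FALSE                       # no diastole after last beat
    next_spike <- c(spike_t[-1], tail(spike_t, 1) + p$mean_bp_s)
    dad_t <- ifelse(dad, twave_t + 0.55 * (next_spike - twave_t), NA_real_)

    t_end <- tail(spike_t, 1) + p$mean_bp_s * 0.9
    n <- ceiling(t_end * fs)
    tt <- (seq_len(n) - 1) / fs
    v <- numeric(n)

    add_local <- function(v, center, sigma, fun) {
      lo <- max(1L, floor((center - 6 * sigma) * fs))
      hi <- min(n, ceiling((center + 6 * sigma) * fs))
      idx <- lo:hi
      v[idx] <- v[idx] + fun(tt[idx])
      v
    }
    for (k in seq_len(p$n_beats)) {
      s <- spike_t[k]
      # biphasic spike with a dominant positive lobe peaking exactly at s
      sig_s <- 0.002
      v <- add_local(v, s, sig_s * 8, function(t) {
        p$spike_amplitude * (exp(-0.5 * ((t - s) / sig_s)^2) -
          0.55 * exp(-0.5 * ((t - s - 2.5 * sig_s) / (1.5 * sig_s))^2))
      })
      v <- add_local(v, twave_t[k], 0.025, function(t)
        gauss_bump(t, twave_t[k], 0.025, p$twave_amplitude))
      if (dad[k]) {
        v <- add_local(v, dad_t[k], 0.02, function(t)
          gauss_bump(t, dad_t[k], 0.02,
                     p$dad_amplitude_fraction * p$spike_amplitude))
      }
    }
    if (p$noise_sd > 0) v <- v + rnorm(n, 0, p$noise_sd)

    truth <- tibble(spike_time_s = spike_t, twave_time_s = twave_t,
                    fpd_ms = fpd, dad = dad, dad_time_s = dad_t)
    structure(list(trace = tibble(time_s = tt, voltage_uv = v),
                   truth = truth, params = p), class = "fp_sim")
  })
}
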