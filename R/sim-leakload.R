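#' Parameters for the SR leak/load protocol simulator
#'
#' Emulates the Shannon-Bers protocol trace: 1 Hz field-stimulated pacing in
#' normal Tyrode to steady state, switch to 0 Na+/0 Ca2+ buffer, dropwise
#' tetracaine (fluorescence falls to the leak baseline), dropwise caffeine
#' (SR store dump, large transient), and return to normal Tyrode.  The
#' planted statistics satisfy the defining ratios exactly before noise.
#'
#' @param pacing_rate_hz Field-stimulation rate (Hz).
#' @param pacing_duration_s Paced phase duration (s); the protocol calls for
#'   at least 20 s to reach steady state.
#' @param f0_diastolic Diastolic fluorescence during pacing (a.u.).
#' @param transient_amplitude_true Planted paced transient amplitude
#'   (dF_trans/F0_diastolic).
#' @param leak_true Planted fractional tetracaine drop
#'   (dF_tet/F0_diastolic), in `[0, 1)`.
#' @param load_true Planted caffeine transient amplitude (dF_caff/F0_leak).
#' @param oscillation_rate Expected spontaneous oscillations per second in
#'   the 0 Na+/0 Ca2+ window before tetracaine (tetracaine abolishes them).
#' @param oscillation_amplitude Oscillation amplitude as dF/F0.
#' @param zero_na_ca_s,tetracaine_s,caffeine_s,recovery_s Phase durations (s).
#' @param sample_rate_hz Trace sampling rate (Hz).
#' @param transient_tau_s Paced-transient decay time constant (s); fast
#'   enough that the trace returns to the diastolic baseline within a beat.
#' @param noise_sd Additive Gaussian noise SD as a fraction of
#'   `f0_diastolic`.
#' @param seed Integer seed.
#' @return A `leakload_sim_params` list.
#' @export
leakload_sim_params <- function(pacing_rate_hz = 1,
                                pacing_duration_s = 20,
                                f0_diastolic = 1.0,
                                transient_amplitude_true = 2.0,
                                leak_true = 0.2,
                                load_true = 3.0,
                                oscillation_rate = 0,
                                oscillation_amplitude = 0.5,
                                zero_na_ca_s = 10,
                                tetracaine_s = 10,
                                caffeine_s = 10,
                                recovery_s = 5,
                                sample_rate_hz = 100,
                                transient_tau_s = 0.12,
                                noise_sd = 0,
                                seed = 1L) {
  p <- list(pacing_rate_hz = pacing_rate_hz,
            pacing_duration_s = pacing_duration_s,
            f0_diastolic = f0_diastolic,
            transient_amplitude_true = transient_amplitude_true,
            leak_true = leak_true, load_true = load_true,
            oscillation_rate = oscillation_rate,
            oscillation_amplitude = oscillation_amplitude,
            zero_na_ca_s = zero_na_ca_s, tetracaine_s = tetracaine_s,
            caffeine_s = caffeine_s, recovery_s = recovery_s,
            sample_rate_hz = sample_rate_hz,
            transient_tau_s = transient_tau_s,
            noise_sd = noise_sd, seed = as.integer(seed))
  if (p$leak_true < 0 || p$leak_true >= 1) {
    abort("leak_true must lie in [0, 1)", class = "myospark_config_error")
  }
  if (p$load_true <= 0) abort("load_true must be positive",
                              class = "myospark_config_error")
  durs <- c(p$pacing_duration_s, p$zero_na_ca_s, p$tetracaine_s,
            p$caffeine_s, p$recovery_s)
  if (any(durs <= 0)) abort("phase durations must be positive",
                            class = "myospark_config_error")
  if (p$pacing_duration_s < 20) {
    warn("pacing_duration_s below the 20 s the protocol requires for steady state")
  }
  structure(p, class = "leakload_sim_params")
}

#' Simulate a whole-cell fluorescence trace for the leak/load protocol
#'
#' @param p A [leakload_sim_params()].
#' @return A `leakload_sim` list: `trace` (tibble `time_s`, `value`),
#'   `phases` (tibble `phase`, `start_s`, `end_s`), `truth` (one-row tibble
#'   of the four planted statistics plus baselines), `oscillations` (tibble
#'   `time_s`, `amplitude`), and `params`.
#' @export
simulate_leakload_trace <- function(p) {
  stopifnot(inherits(p, "leakload_sim_params"))
  fs <- p$sample_rate_hz
  t_pace <- p$pacing_duration_s
  t1 <- t_pace + p$zero_na_ca_s          # tetracaine start
  t2 <- t1 + p$tetracaine_s              # caffeine start
  t3 <- t2 + p$caffeine_s                # recovery start
  t_end <- t3 + p$recovery_s
  tt <- seq(0, t_end - 1 / fs, by = 1 / fs)
  f0 <- p$f0_diastolic
  f_leak <- f0 * (1 - p$leak_true)
  caff_peak <- f_leak * (1 + p$load_true)

  withr::with_seed(p$seed, {
    v <- rep(f0, length(tt))

    ## paced transients: linear 30 ms rise, exponential decay
    period <- 1 / p$pacing_rate_hz
    rise <- 0.03
    onsets <- seq(0.2, t_pace - period + 0.2, by = period)
    for (on in onsets) {
      peak_t <- round((on + rise) * fs) / fs   # snap peak to the grid
      on_s <- peak_t - rise
      idx <- tt >= on_s & tt < on_s + period - 0.05
      ts <- tt[idx]
      g <- ifelse(ts < peak_t, (ts - on_s) / rise,
                  exp(-(ts - peak_t) / p$transient_tau_s))
      v[idx] <- v[idx] + f0 * p$transient_amplitude_true * pmax(0, g)
    }

    ## 0 Na+/0 Ca2+ oscillations, pre-tetracaine only
    osc <- tibble(time_s = numeric(), amplitude = numeric())
    n_osc <- rpois(1, p$oscillation_rate * p$zero_na_ca_s)
    if (n_osc > 0) {
      lo <- t_pace + 0.5
      hi <- t1 - 1.5                     # keep the pre-tetracaine baseline clean
      if (hi > lo) {
        on_t <- sort(runif(n_osc, lo, hi))
        # enforce a minimum separation so events stay resolvable
        keep <- c(TRUE, diff(on_t) > 0.5)
        on_t <- on_t[keep]
        for (on in on_t) {
          peak_t <- round((on + 0.02) * fs) / fs
          idx <- tt >= peak_t - 0.02 & tt < peak_t + 0.5
          ts <- tt[idx]
          g <- ifelse(ts < peak_t, (ts - (peak_t - 0.02)) / 0.02,
                      exp(-(ts - peak_t) / 0.08))
          v[idx] <- v[idx] + f0 * p$oscillation_amplitude * pmax(0, g)
        }
        osc <- tibble(time_s = on_t, amplitude = p$oscillation_amplitude)
      }
    }

    ## tetracaine: exponential fall from f0 to f_leak
    idx <- tt >= t1 & tt < t2
    v[idx] <- f_leak + (f0 - f_leak) * exp(-(tt[idx] - t1) / 0.5)

    ## caffeine: linear 0.5 s rise to the store-dump peak, slow decay
    rise_c <- 0.5
    idx <- tt >= t2 & tt < t2 + rise_c
    v[idx] <- f_leak + (caff_peak - f_leak) * (tt[idx] - t2) / rise_c
    idx <- tt >= t2 + rise_c & tt < t3
    v[idx] <- f_leak + (caff_peak - f_leak) * exp(-(tt[idx] - t2 - rise_c) / 2)

    ## recovery toward the NT diastolic level
    idx <- tt >= t3
    v_t3 <- f_leak + (caff_peak - f_leak) * exp(-(t3 - t2 - rise_c) / 2)
    v[idx] <- f0 + (v_t3 - f0) * exp(-(tt[idx] - t3) / 0.3)

    if (p$noise_sd > 0) v <- v + rnorm(length(v), 0, p$noise_sd * f0)
    v <- pmax(v, 1e-9)

    phases <- tibble(
      phase = c("paced_nt", "zero_na_ca", "tetracaine", "caffeine",
                "recovery_nt"),
      start_s = c(0, t_pace, t1, t2, t3),
      end_s = c(t_pace, t1, t2, t3, t_end))

    truth <- tibble(
      transient_amplitude = p$transient_amplitude_true,
      leak = p$leak_true, load = p$load_true,
      fractional_release = p$transient_amplitude_true / p$load_true,
      f0_diastolic = f0, f0_leak = f_leak,
      n_oscillations = nrow(osc))

    structure(list(trace = tibble(time_s = tt, value = v),
                   phases = phases, truth = truth, oscillations = osc,
                   params = p), class = "leakload_sim")
  })
}
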