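#' Configuration for the synthetic confocal line-scan generator
#'
#' Builds and validates the parameter set used by [simulate_linescan()].
#' Defaults mirror typical fluo-4 confocal acquisition of iPSC-derived
#' cardiomyocytes: 0.155 um pixels and at least 500 lines per second, so the
#' time step is at most 2 ms.
#'
#' @param scan_length_um Physical scan length (um).
#' @param pixel_size_um Spatial sampling (um/pixel).
#' @param line_rate_hz Lines per second.
#' @param duration_s Recording length (s).
#' @param baseline_f0 Baseline fluorescence (a.u.).
#' @param noise_sd Additive Gaussian noise SD as a fraction of `baseline_f0`.
#' @param spark_rate Expected sparks per 100 um per second.
#' @param spark_amplitude_mean,spark_amplitude_sd Planted spark amplitude
#'   (dF/F0) mean and SD.
#' @param spark_fwhm_um_mean,spark_fwhm_um_sd Planted spatial full width at
#'   half maximum (um), mean and SD.
#' @param spark_fdhm_ms_mean,spark_fdhm_ms_sd Planted temporal full duration
#'   at half maximum (ms), mean and SD.
#' @param transient_rate_hz Spontaneous beating rate (Hz); paced transients
#'   are rendered as a regular train at this rate.
#' @param transient_amplitude Amplitude (dF/F0) of each whole-line transient.
#'   A vector is recycled across beats, so `c(1, 2)` plants amplitude
#'   alternans.
#' @param transient_fdhm_ms Temporal half-maximum duration of transients (ms).
#' @param wave_rate_per_s Expected diastolic wave count per second.
#' @param wave_extent_fraction Fraction of the scan length a wave traverses
#'   (1 renders a whole-cell wave, smaller values render wavelets).
#' @param wave_amplitude Wave amplitude (dF/F0).
#' @param wave_fdhm_ms Temporal half-maximum duration of the wave at a fixed
#'   position (ms).
#' @param wave_velocity_um_s Wave propagation velocity (um/s).
#' @param seed Integer seed; together with the config it fully determines the
#'   output.
#'
#' @return A `linescan_sim_config` list.
#' @export
linescan_sim_config <- function(scan_length_um = 50,
                                pixel_size_um = 0.155,
                                line_rate_hz = 500,
                                duration_s = 4,
                                baseline_f0 = 100,
                                noise_sd = 0.05,
                                spark_rate = 2,
                                spark_amplitude_mean = 1.0,
                                spark_amplitude_sd = 0.2,
                                spark_fwhm_um_mean = 2.0,
                                spark_fwhm_um_sd = 0.3,
                                spark_fdhm_ms_mean = 30,
                                spark_fdhm_ms_sd = 5,
                                transient_rate_hz = 0,
                                transient_amplitude = 2.0,
                                transient_fdhm_ms = 250,
                                wave_rate_per_s = 0,
                                wave_extent_fraction = 1.0,
                                wave_amplitude = 1.5,
                                wave_fdhm_ms = 250,
                                wave_velocity_um_s = 50,
                                seed = 1L) {
  cfg <- list(
    scan_length_um = scan_length_um, pixel_size_um = pixel_size_um,
    line_rate_hz = line_rate_hz, duration_s = duration_s,
    baseline_f0 = baseline_f0, noise_sd = noise_sd,
    spark_rate = spark_rate,
    spark_amplitude_mean = spark_amplitude_mean,
    spark_amplitude_sd = spark_amplitude_sd,
    spark_fwhm_um_mean = spark_fwhm_um_mean,
    spark_fwhm_um_sd = spark_fwhm_um_sd,
    spark_fdhm_ms_mean = spark_fdhm_ms_mean,
    spark_fdhm_ms_sd = spark_fdhm_ms_sd,
    transient_rate_hz = transient_rate_hz,
    transient_amplitude = transient_amplitude,
    transient_fdhm_ms = transient_fdhm_ms,
    wave_rate_per_s = wave_rate_per_s,
    wave_extent_fraction = wave_extent_fraction,
    wave_amplitude = wave_amplitude,
    wave_fdhm_ms = wave_fdhm_ms,
    wave_velocity_um_s = wave_velocity_um_s,
    seed = as.integer(seed)
  )
  if (cfg$scan_length_um <= 0 || cfg$duration_s <= 0) {
    abort("scan_length_um and duration_s must be positive",
          class = "myospark_config_error")
  }
  if (cfg$pixel_size_um <= 0 || cfg$line_rate_hz <= 0) {
    abort("pixel_size_um and line_rate_hz must be positive",
          class = "myospark_config_error")
  }
  rates <- c(cfg$spark_rate, cfg$transient_rate_hz, cfg$wave_rate_per_s)
  if (any(rates < 0) || cfg$noise_sd < 0) {
    abort("event rates and noise_sd must be nonnegative",
          class = "myospark_config_error")
  }
  if (cfg$wave_extent_fraction <= 0 || cfg$wave_extent_fraction > 1) {
    abort("wave_extent_fraction must lie in (0, 1]",
          class = "myospark_config_error")
  }
  structure(cfg, class = "linescan_sim_config")
}

# Linear-rise / exponential-decay temporal kernel, unit peak at
# t = onset + rise.  tau is chosen in closed form so the width at half
# maximum equals fdhm: half-max crossings at onset + rise/2 (rising) and
# peak + tau*log(2) (falling), hence tau = (fdhm - rise/2) / log(2).
event_time_kernel <- function(t, onset_s, fdhm_ms, rise_ms = 5) {
  rise <- rise_ms / 1000
  fdhm <- fdhm_ms / 1000
  if (fdhm <= rise / 2) {
    abort("fdhm_ms must exceed half the rise time",
          class = "myospark_config_error")
  }
  tau <- (fdhm - rise / 2) / log(2)
  peak <- onset_s + rise
  g <- numeric(length(t))
  up <- t >= onset_s & t < peak
  g[up] <- (t[up] - onset_s) / rise
  dn <- t >= peak
  g[dn] <- exp(-(t[dn] - peak) / tau)
  g
}

#' Simulate a fluo-4 line-scan (X-T) image with planted ground truth
#'
#' Renders a space-by-time fluorescence grid containing calcium sparks
#' (separable spatial-Gaussian by linear-rise/exponential-decay temporal
#' kernels), spatially uniform paced transients, and propagating diastolic
#' waves or wavelets, plus additive Gaussian noise.  Every planted event is
#' returned in a ground-truth table; spark centers and peak times are snapped
#' to the sampling grid so the rendered peak equals the planted amplitude up
#' to discretization.
#'
#' @param cfg A [linescan_sim_config()].
#' @return A `linescan_sim` list with elements `image` (a [linescan()]),
#'   `truth` (tibble of planted events, sorted by onset: `kind`,
#'   `position_um`, `onset_s`, `amplitude`, `fwhm_um`, `fdhm_ms`,
#'   `extent_fraction`) and `config`.
#' @export
simulate_linescan <- function(cfg) {
  stopifnot(inherits(cfg, "linescan_sim_config"))
  n_x <- max(1L, round(cfg$scan_length_um / cfg$pixel_size_um))
  n_t <- max(1L, round(cfg$duration_s * cfg$line_rate_hz))
  x <- (seq_len(n_x) - 0.5) * cfg$pixel_size_um
  t <- (seq_len(n_t) - 1) / cfg$line_rate_hz
  rise_s <- 5 / 1000

  withr::with_seed(cfg$seed, {
    rel <- matrix(0, n_x, n_t)  # dF/F0 contribution
    truth <- list()

    ## paced / spontaneous transients: regular train
    transient_windows <- NULL
    if (cfg$transient_rate_hz > 0) {
      period <- 1 / cfg$transient_rate_hz
      onsets <- seq(0.2, cfg$duration_s - 0.1, by = period)
      amps <- rep_len(cfg$transient_amplitude, length(onsets))
      for (k in seq_along(onsets)) {
        on_k <- t[which.min(abs(t - (onsets[k] + 0.02)))] - 0.02
        g <- event_time_kernel(t, on_k, cfg$transient_fdhm_ms, rise_ms = 20)
        rel <- rel + amps[k] * matrix(g, n_x, n_t, byrow = TRUE)
        truth[[length(truth) + 1L]] <- tibble(
          kind = "transient", position_um = cfg$scan_length_um / 2,
          onset_s = on_k, amplitude = amps[k], fwhm_um = NA_real_,
          fdhm_ms = cfg$transient_fdhm_ms, extent_fraction = 1.0)
      }
      # window runs to the 5% decay point of the transient kernel
      tau_tr <- (cfg$transient_fdhm_ms / 1000 - 0.01) / log(2)
      transient_windows <- cbind(onsets - 0.02,
                                 onsets + 0.02 + tau_tr * log(20))
    }

    in_transient <- function(tt) {
      if (is.null(transient_windows)) return(rep(FALSE, length(tt)))
      out <- rep(FALSE, length(tt))
      for (i in seq_len(nrow(transient_windows))) {
        out <- out | (tt >= transient_windows[i, 1] - 0.05 &
                        tt <= transient_windows[i, 2] + 0.05)
      }
      out
    }

    ## sparks
    n_sparks <- rpois(1, cfg$spark_rate * cfg$scan_length_um / 100 * cfg$duration_s)
    if (n_sparks > 0) {
      for (k in seq_len(n_sparks)) {
        pos <- runif(1, 2, cfg$scan_length_um - 2)
        pos <- x[which.min(abs(x - pos))]           # snap to pixel center
        onset <- runif(1, 0.05, cfg$duration_s - 0.2)
        # keep planted sparks diastolic when transients are present
        tries <- 0
        while (any(in_transient(onset)) && tries < 50) {
          onset <- runif(1, 0.05, cfg$duration_s - 0.2); tries <- tries + 1
        }
        peak_t <- t[which.min(abs(t - (onset + rise_s)))]
        onset <- peak_t - rise_s
        amp <- max(0.1 * cfg$spark_amplitude_mean,
                   rnorm(1, cfg$spark_amplitude_mean, cfg$spark_amplitude_sd))
        fwhm <- max(0.5, rnorm(1, cfg$spark_fwhm_um_mean, cfg$spark_fwhm_um_sd))
        fdhm <- max(8, rnorm(1, cfg$spark_fdhm_ms_mean, cfg$spark_fdhm_ms_sd))
        sig <- fwhm / (2 * sqrt(2 * log(2)))
        gx <- exp(-0.5 * ((x - pos) / sig)^2)
        gt <- event_time_kernel(t, onset, fdhm)
        rel <- rel + amp * outer(gx, gt)
        truth[[length(truth) + 1L]] <- tibble(
          kind = "spark", position_um = pos, onset_s = onset,
          amplitude = amp, fwhm_um = fwhm, fdhm_ms = fdhm,
          extent_fraction = NA_real_)
      }
    }

    ## diastolic waves / wavelets
    n_waves <- rpois(1, cfg$wave_rate_per_s * cfg$duration_s)
    if (n_waves > 0) {
      ext_um <- cfg$wave_extent_fraction * cfg$scan_length_um
      travel_s <- ext_um / cfg$wave_velocity_um_s
      for (k in seq_len(n_waves)) {
        onset <- runif(1, 0.05, max(0.06, cfg$duration_s - travel_s - 0.3))
        tries <- 0
        while (any(in_transient(c(onset, onset + travel_s))) && tries < 100) {
          onset <- runif(1, 0.05, max(0.06, cfg$duration_s - travel_s - 0.3))
          tries <- tries + 1
        }
        x0 <- if (cfg$wave_extent_fraction >= 1) 0 else
          runif(1, 0, cfg$scan_length_um - ext_um)
        covered <- x >= x0 & x <= x0 + ext_um
        for (i in which(covered)) {
          on_i <- onset + (x[i] - x0) / cfg$wave_velocity_um_s
          rel[i, ] <- rel[i, ] +
            cfg$wave_amplitude * event_time_kernel(t, on_i, cfg$wave_fdhm_ms)
        }
        truth[[length(truth) + 1L]] <- tibble(
          kind = if (cfg$wave_extent_fraction >= 0.9) "wave" else "wavelet",
          position_um = x0 + ext_um / 2, onset_s = onset,
          amplitude = cfg$wave_amplitude, fwhm_um = NA_real_,
          fdhm_ms = cfg$wave_fdhm_ms,
          extent_fraction = cfg$wave_extent_fraction)
      }
    }

    values <- cfg$baseline_f0 * (1 + rel)
    if (cfg$noise_sd > 0) {
      values <- values + rnorm(n_x * n_t, 0, cfg$noise_sd * cfg$baseline_f0)
      values[values < 1e-6] <- 1e-6
    }

    truth <- if (length(truth)) dplyr::arrange(dplyr::bind_rows(truth), .data$onset_s)
    else tibble(kind = character(), position_um = numeric(),
                onset_s = numeric(), amplitude = numeric(),
                fwhm_um = numeric(), fdhm_ms = numeric(),
                extent_fraction = numeric())

    structure(list(
      image = linescan(values, pixel_size_um = cfg$pixel_size_um,
                       line_rate_hz = cfg$line_rate_hz),
      truth = truth, config = cfg), class = "linescan_sim")
  })
}
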