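scan_config <- function(kind, seed) {
  linescan_sim_config(
    scan_length_um = 30, duration_s = 2, noise_sd = 0.05, spark_rate = 2,
    transient_rate_hz = 1, transient_fdhm_ms = 150,
    wave_rate_per_s = if (kind == "scw") 1.2 else 0,
    wave_velocity_um_s = 250, wave_fdhm_ms = 150,
    transient_amplitude = if (kind == "other") c(1, 2) else 2,
    seed = seed)
}

test_that("segment_transients recovers a regular paced train", {
  sim <- simulate_linescan(scan_config("normal", 41))
  norm <- normalize_linescan(sim$image)
  seg <- segment_transients(norm)
  tr_truth <- sim$truth[sim$truth$kind == "transient", ]
  expect_identical(nrow(seg$transients), nrow(tr_truth))
  expect_equal(seg$transients$peak_s, tr_truth$onset_s + 0.02,
               tolerance = 0.05)
  bp <- seg$transients$beat_period_s
  expect_equal(bp[is.finite(bp)], rep(1, sum(is.finite(bp))),
               tolerance = 0.05)
})

test_that("quiescent scans yield no transients and full diastole", {
  sim <- simulate_linescan(linescan_sim_config(
    scan_length_um = 30, duration_s = 2, noise_sd = 0.05,
    spark_rate = 2, seed = 42))
  norm <- normalize_linescan(sim$image)
  seg <- segment_transients(norm)
  expect_identical(nrow(seg$transients), 0L)
  expect_equal(sum(seg$diastolic_intervals$end_s -
                     seg$diastolic_intervals$start_s), 2)
})

test_that("a propagating wave is not mistaken for a paced transient", {
  # wave only, no pacing: spatial half-max crossing times are dispersed
  sim <- simulate_linescan(linescan_sim_config(
    scan_length_um = 30, duration_s = 2, noise_sd = 0.02, spark_rate = 0,
    wave_rate_per_s = 0.8, wave_velocity_um_s = 100, wave_fdhm_ms = 150,
    seed = 43))
  stopifnot(any(sim$truth$kind == "wave"))
  norm <- normalize_linescan(sim$image)
  seg <- segment_transients(norm)
  expect_identical(nrow(seg$transients), 0L)
  waves <- detect_waves(norm, seg)
  expect_gte(nrow(waves), 1)
})

test_that("wave extent separates whole-cell waves from wavelets", {
  for (ext in c(1.0, 0.4)) {
    sim <- simulate_linescan(linescan_sim_config(
      scan_length_um = 30, duration_s = 2, noise_sd = 0.02, spark_rate = 0,
      wave_rate_per_s = 0.8, wave_extent_fraction = ext,
      wave_velocity_um_s = 100, wave_fdhm_ms = 150, seed = 44))
    truth_kind <- unique(sim$truth$kind[sim$truth$kind != "spark"])
    norm <- normalize_linescan(sim$image)
    seg <- segment_transients(norm)
    waves <- detect_waves(norm, seg)
    expect_gte(nrow(waves), 1)
    if (ext == 1.0) expect_true("wave" %in% waves$kind)
    else expect_true(all(waves$kind == "wavelet"))
    expect_setequal(unique(waves$kind), truth_kind)
  }
})

test_that("classification precedence: waves dominate irregularity", {
  seg <- structure(list(
    transients = tibble::tibble(onset_s = c(0.2, 1.2), peak_s = c(0.22, 1.22),
                                end_s = c(0.8, 1.8), amplitude = c(1, 2),
                                beat_period_s = c(1, NA)),
    diastolic_intervals = tibble::tibble(start_s = 0, end_s = 0.15),
    duration_s = 2), class = "transient_segmentation")
  waves <- tibble::tibble(onset_s = 0.05, amplitude = 1.5,
                          extent_fraction = 1, kind = "wave")
  cls <- classify_linescan(seg, waves)
  expect_identical(cls$label, "scw")
  no_waves <- waves[0, ]
  cls2 <- classify_linescan(seg, no_waves)
  expect_identical(cls2$label, "other")  # amplitude CV way above tolerance
})

test_that("wave_stats reports NA, not zero, when no waves were seen", {
  empty <- tibble::tibble(onset_s = numeric(), amplitude = numeric(),
                          extent_fraction = numeric(), kind = character())
  ws <- wave_stats(empty, 3)
  expect_identical(ws$n_waves, 0L)
  expect_true(is.na(ws$mean_amplitude))
  expect_true(is.na(ws$frequency_per_s))
  expect_error(wave_stats(empty, 0), class = "myospark_input_error")
})

test_that("classification is deterministic", {
  sim <- simulate_linescan(scan_config("scw", 45))
  a <- classify_scan(sim$image)
  b <- classify_scan(sim$image)
  expect_identical(a$label, b$label)
  expect_identical(a$evidence, b$evidence)
})
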