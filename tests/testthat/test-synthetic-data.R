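test_that("line-scan simulation is deterministic given the config", {
  cfg <- linescan_sim_config(duration_s = 1, spark_rate = 5, seed = 11)
  a <- simulate_linescan(cfg)
  b <- simulate_linescan(cfg)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$truth, b$truth)
})

test_that("config validation rejects nonsense parameters", {
  expect_error(linescan_sim_config(pixel_size_um = 0),
               class = "myospark_config_error")
  expect_error(linescan_sim_config(spark_rate = -1),
               class = "myospark_config_error")
  expect_error(linescan_sim_config(wave_extent_fraction = 0),
               class = "myospark_config_error")
  expect_error(fp_sim_params(dad_amplitude_fraction = 1.5),
               class = "myospark_config_error")
  expect_error(fp_sim_params(mean_bp_s = 0.2, fpd_ms_mean = 300),
               class = "myospark_config_error")
  expect_error(leakload_sim_params(leak_true = 1.2),
               class = "myospark_config_error")
})

test_that("noise-free rendered spark peak equals the planted amplitude within 1%", {
  cfg <- linescan_sim_config(duration_s = 2, noise_sd = 0, spark_rate = 3,
                             spark_amplitude_sd = 0, seed = 3)
  sim <- simulate_linescan(cfg)
  sparks <- sim$truth[sim$truth$kind == "spark", ]
  expect_gt(nrow(sparks), 0)
  dff0 <- sim$image$values / cfg$baseline_f0 - 1
  for (k in seq_len(nrow(sparks))) {
    i <- round(sparks$position_um[k] / cfg$pixel_size_um + 0.5)
    j <- round((sparks$onset_s[k] + 0.005) * cfg$line_rate_hz) + 1
    expect_lt(abs(dff0[i, j] - sparks$amplitude[k]) / sparks$amplitude[k],
              0.01)
  }
})

test_that("spark truth table is sorted by onset and events stay in bounds", {
  sim <- simulate_linescan(linescan_sim_config(spark_rate = 8, seed = 5))
  expect_false(is.unsorted(sim$truth$onset_s))
  expect_true(all(sim$truth$position_um >= 0 &
                    sim$truth$position_um <= 50))
  expect_true(all(sim$truth$onset_s >= 0 & sim$truth$onset_s <= 4))
})

test_that("line-scan TIFF round trip preserves values and calibration", {
  sim <- simulate_linescan(linescan_sim_config(duration_s = 0.5,
                                               scan_length_um = 10, seed = 2))
  path <- file.path(tempdir(), "roundtrip.tiff")
  write_linescan(sim$image, path)
  back <- read_linescan(path)
  expect_equal(back$values, sim$image$values, tolerance = 1e-6)
  expect_equal(back$pixel_size_um, sim$image$pixel_size_um)
  expect_equal(back$line_rate_hz, sim$image$line_rate_hz)
  unlink(path); unlink(paste0(path, ".json"))
})

test_that("noise-free leak/load trace realizes the planted levels exactly", {
  p <- leakload_sim_params(noise_sd = 0, seed = 1)
  sim <- simulate_leakload_trace(p)
  v <- sim$trace$value
  tt <- sim$trace$time_s
  f0 <- p$f0_diastolic
  # pre-tetracaine 0Na/0Ca plateau sits at f0, tetracaine floor at f0(1-leak)
  w <- sim$phases
  tet <- v[tt >= w$start_s[w$phase == "tetracaine"] &
             tt < w$end_s[w$phase == "tetracaine"]]
  expect_equal(min(tet), f0 * (1 - p$leak_true), tolerance = 1e-3)
  caff <- v[tt >= w$start_s[w$phase == "caffeine"] &
              tt < w$end_s[w$phase == "caffeine"]]
  expect_equal(max(caff), f0 * (1 - p$leak_true) * (1 + p$load_true),
               tolerance = 1e-6)
})

test_that("field-potential truth has one row per beat with snapped times", {
  p <- fp_sim_params(n_beats = 10, seed = 4)
  sim <- simulate_field_potential(p)
  expect_identical(nrow(sim$truth), 10L)
  expect_equal(sim$truth$spike_time_s * p$sampling_hz,
               round(sim$truth$spike_time_s * p$sampling_hz))
  expect_false(sim$truth$dad[10])  # no diastole rendered after the last beat
})

test_that("C_T generator plants exact expression effects when noiseless", {
  tab <- generate_ct_table(
    genes = c("REF", "G1", "G2"), samples = c("s1", "s2"),
    reference_gene = "REF",
    effect_map = c(G1 = 2, G2 = -1),
    reference_ct = 20, noise_sd = 0, seed = 1)
  nd <- neg_delta_ct(tab, "REF", bin_thresholds = c(-0.5, 1))
  expect_true(all(nd$neg_delta_ct[nd$gene == "G1"] == 2))
  expect_true(all(nd$neg_delta_ct[nd$gene == "G2"] == -1))
  expect_true(all(nd$neg_delta_ct[nd$gene == "REF"] == 0))
})
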