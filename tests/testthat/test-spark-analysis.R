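test_that("boxcar smoothing matches the loop-based oracle", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      m <- matrix(rnorm(30 * 40), 30, 40)
      expect_equal(myospark:::boxcar3(m), oracle_boxcar3(m))
    }
  })
})

test_that("normalization recovers a flat baseline and known noise level", {
  withr::with_seed(7, {
    f0 <- 100
    v <- matrix(f0 * (1 + rnorm(64 * 400, 0, 0.05)), 64, 400)
    img <- linescan(v, pixel_size_um = 0.155, line_rate_hz = 500)
    norm <- normalize_linescan(img)
    expect_equal(norm$f0_profile, rep(f0, 64), tolerance = 0.02)
    expect_equal(norm$background_sd, 0.05, tolerance = 0.015)
    expect_lt(abs(norm$background_mean), 0.01)
  })
})

test_that("normalization errors on nonpositive baseline", {
  v <- matrix(1, 4, 10); v[2, ] <- 0
  img <- linescan(v, 0.155, 500)
  expect_error(normalize_linescan(img),
               class = "myospark_normalization_error")
})

test_that("raising the detection criteria never adds detections", {
  withr::with_seed(31, {
    dff0 <- matrix(rnorm(64 * 200, 0, 1), 64, 200)
    dff0[20:24, 50:60] <- dff0[20:24, 50:60] + 6
    norm <- make_norm(dff0)
    low <- detect_sparks(norm, spark_detection_config(criteria = 3.0))
    high <- detect_sparks(norm, spark_detection_config(criteria = 4.5))
    expect_lte(nrow(high), nrow(low))
    # every high-criteria peak persists at the lower criteria
    expect_true(all(paste(high$peak_i, high$peak_j) %in%
                      paste(low$peak_i, low$peak_j)))
  })
})

test_that("masked regions are excluded from detection", {
  dff0 <- matrix(0, 32, 100)
  dff0[10:14, 20:30] <- 5
  dff0[10:14, 70:80] <- 5
  mask <- matrix(TRUE, 32, 100); mask[, 60:100] <- FALSE
  norm <- make_norm(dff0, mask = mask)
  cand <- detect_sparks(norm)
  expect_identical(nrow(cand), 1L)
  expect_true(cand$peak_j <= 60)
})

test_that("morphometry is exact on an analytic noise-free spark", {
  # separable Gaussian (space) x linear-rise/exponential-decay (time)
  # grid chosen so the kernel peak falls exactly on a sample
  nx <- 129; nt <- 1000
  px <- 0.155; fs <- 1000
  x <- (seq_len(nx) - 0.5) * px
  tt <- (seq_len(nt) - 1) / fs
  amp <- 1.0; fwhm <- 2.0; fdhm <- 30
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  x0 <- x[60]; t_on <- tt[400]
  tau <- (fdhm / 1000 - 0.0025) / log(2)
  gt <- ifelse(tt < t_on, 0,
               ifelse(tt < t_on + 0.005, (tt - t_on) / 0.005,
                      exp(-(tt - t_on - 0.005) / tau)))
  dff0 <- amp * exp(-0.5 * ((x - x0) / sig)^2) %o% gt
  norm <- make_norm(dff0, bg_mean = 0, bg_sd = 0.02,
                    pixel_size_um = px, line_rate_hz = fs)
  ev <- measure_sparks(norm)
  expect_identical(nrow(ev), 1L)
  # the smoothed argmax may sit one line into the slow decay, so the raw
  # amplitude there is within the one-line discretization of the peak
  expect_equal(ev$amplitude, amp, tolerance = 0.03)
  expect_equal(ev$fwhm_um, fwhm, tolerance = 0.05)
  expect_equal(ev$fdhm_ms, fdhm, tolerance = 2)
  expect_false(ev$truncated)
})

test_that("events cut by the image edge are flagged truncated", {
  dff0 <- matrix(0, 32, 100)
  dff0[1:4, 40:60] <- 6   # touches the spatial edge: no left half-max crossing
  norm <- make_norm(dff0)
  ev <- measure_sparks(norm)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$truncated)
  expect_true(is.na(ev$fwhm_um))
})

test_that("spark frequency follows events / (100 um) / analyzed seconds", {
  dff0 <- matrix(0, 100, 500)
  dff0[40:44, 100:110] <- 5
  dff0[60:64, 300:310] <- 5
  norm <- make_norm(dff0, pixel_size_um = 0.2, line_rate_hz = 500)
  ev <- measure_sparks(norm)
  expect_identical(nrow(ev), 2L)
  # 100 px * 0.2 um = 20 um scan, 500 lines / 500 Hz = 1 s
  expect_equal(spark_frequency(ev, norm), 2 / (20 / 100) / 1)
})

test_that("summary KDEs integrate to one and glance mirrors stats", {
  withr::with_seed(13, {
    sim <- simulate_linescan(linescan_sim_config(spark_rate = 8, seed = 13))
    norm <- normalize_linescan(sim$image)
    ev <- measure_sparks(norm)
    s <- summarize_sparks(ev, norm)
    for (k in names(s$kde)) {
      d <- s$kde[[k]]
      area <- sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
      expect_equal(area, 1, tolerance = 0.01)
    }
    expect_identical(generics::glance(s), s$stats)
    td <- generics::tidy(s)
    expect_true(all(c("statistic", "value") %in% names(td)))
  })
})

test_that("duration-amplitude r-squared matches squared correlation", {
  withr::with_seed(17, {
    ev <- tibble::tibble(amplitude = runif(30, 0.5, 2))
    ev$fdhm_ms <- 20 + 5 * ev$amplitude + rnorm(30, 0, 3)
    ev$truncated <- FALSE
    expect_equal(fdhm_amplitude_r2(ev),
                 cor(ev$amplitude, ev$fdhm_ms)^2, tolerance = 1e-12)
  })
  expect_error(fdhm_amplitude_r2(tibble::tibble(
    amplitude = 1, fdhm_ms = 2, truncated = FALSE)),
    class = "myospark_input_error")
})
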