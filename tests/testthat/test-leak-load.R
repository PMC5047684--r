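test_that("annotated segmentation reproduces the planted phase table", {
  sim <- simulate_leakload_trace(leakload_sim_params(seed = 1))
  seg <- segment_phases(sim$trace, sim$phases)
  expect_equal(as.data.frame(seg), as.data.frame(sim$phases))
})

test_that("switch-time annotations build ordered phases and are validated", {
  sim <- simulate_leakload_trace(leakload_sim_params(seed = 1))
  ann <- c(zero_na_ca_start = 20, tetracaine_start = 30,
           caffeine_start = 40, recovery_start = 50)
  seg <- segment_phases(sim$trace, ann)
  expect_identical(seg$phase,
                   c("paced_nt", "zero_na_ca", "tetracaine", "caffeine",
                     "recovery_nt"))
  expect_equal(seg$start_s[-1], unname(ann))
  bad <- ann; bad["caffeine_start"] <- 10
  expect_error(segment_phases(sim$trace, bad),
               class = "myospark_input_error")
  expect_error(segment_phases(sim$trace, ann[-2]),
               class = "myospark_input_error")
})

test_that("fallback segmentation lands within 0.2 s of the protocol switches", {
  sim <- simulate_leakload_trace(leakload_sim_params(noise_sd = 0.01,
                                                     seed = 2))
  seg <- segment_phases(sim$trace)
  expect_equal(seg$start_s, sim$phases$start_s, tolerance = 0.2)
})

test_that("statistics recover planted truth on a noisy trace", {
  p <- leakload_sim_params(transient_amplitude_true = 2, leak_true = 0.2,
                           load_true = 3, noise_sd = 0.01, seed = 3)
  sim <- simulate_leakload_trace(p)
  res <- analyze_leakload(sim$trace, sim$phases)$result
  expect_equal(res$transient_amplitude, 2, tolerance = 0.1)
  expect_equal(res$leak, 0.2, tolerance = 0.1)
  expect_equal(res$load, 3, tolerance = 0.1)
  expect_equal(res$fractional_release, 2 / 3, tolerance = 0.05)
})

test_that("negative computed leak is clamped to zero with a warning", {
  # flat trace through tetracaine, deliberately higher than the declared
  # pre-tetracaine window via a crafted step
  tt <- seq(0, 60 - 0.01, by = 0.01)
  v <- rep(1, length(tt))
  v[tt >= 30 & tt < 40] <- 1.2          # tetracaine window sits above baseline
  v[tt >= 40 & tt < 45] <- 4            # caffeine peak
  # paced beats so transient_amplitude works
  for (on in seq(0.2, 19.2, by = 1)) {
    idx <- tt >= on & tt < on + 0.5
    v[idx] <- v[idx] + 2 * exp(-(tt[idx] - on) / 0.12)
  }
  trace <- tibble::tibble(time_s = tt, value = v)
  ann <- c(zero_na_ca_start = 20, tetracaine_start = 30,
           caffeine_start = 40, recovery_start = 45)
  seg <- segment_phases(trace, ann)
  expect_warning(lk <- sr_leak(trace, seg), "clamped")
  expect_identical(lk$leak, 0)
})

test_that("protocol order is enforced: load needs the tetracaine floor", {
  sim <- simulate_leakload_trace(leakload_sim_params(seed = 1))
  seg <- segment_phases(sim$trace, sim$phases)
  expect_error(sr_load(sim$trace, seg, NA_real_),
               class = "myospark_protocol_error")
})

test_that("planted 0Na/0Ca oscillations are detected", {
  p <- leakload_sim_params(oscillation_rate = 0.4, noise_sd = 0.005,
                           seed = 8)
  sim <- simulate_leakload_trace(p)
  res <- analyze_leakload(sim$trace, sim$phases)
  expect_identical(res$result$n_oscillations, nrow(sim$oscillations))
  if (nrow(sim$oscillations) > 0) {
    d <- vapply(sim$oscillations$time_s, function(t0)
      min(abs(res$oscillations$time_s - t0)), numeric(1))
    expect_true(all(d < 0.1))
  }
})

test_that("tidy and glance expose the result tibble", {
  sim <- simulate_leakload_trace(leakload_sim_params(seed = 1))
  res <- analyze_leakload(sim$trace, sim$phases, cell_id = "c1")
  g <- generics::glance(res)
  expect_identical(g$cell_id, "c1")
  td <- generics::tidy(res)
  expect_true(all(c("statistic", "value") %in% names(td)))
  expect_true("leak" %in% td$statistic)
})
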