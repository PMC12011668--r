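# Acquisition simulator: mixing, noise, leading-edge trigger, datasets.

test_that("mixing is commutative, additive in integral, and grid-checked", {
  g <- time_grid(256)
  p1 <- bi_exponential_pulse(scintillator("BGO"), 300, g, start_time = 20)
  p2 <- bi_exponential_pulse(scintillator("EJ200"), 211, g, start_time = 20)
  z <- pulse_waveform(numeric(256), g)
  expect_equal(mix_pulses(p1, z)$samples, p1$samples)
  expect_equal(mix_pulses(p1, p2)$samples, mix_pulses(p2, p1)$samples)
  expect_equal(pulse_integral(mix_pulses(p1, p2)),
               pulse_integral(p1) + pulse_integral(p2))
  p3 <- bi_exponential_pulse(scintillator("BGO"), 300, time_grid(128))
  expect_error(mix_pulses(p1, p3), "grids differ")
})

test_that("additive noise has the requested first and second moments", {
  g <- time_grid(1000)
  p <- bi_exponential_pulse(scintillator("LGSO"), 400, g, start_time = 100)
  expect_identical(add_awgn(p, 0)$samples, p$samples)
  expect_error(add_awgn(p, -1), ">= 0")

  n1 <- add_awgn(p, 2.5, seed = 99)
  n2 <- add_awgn(p, 2.5, seed = 99)
  expect_identical(n1$samples, n2$samples)

  # 1e6 draws: mean within 4*sigma/sqrt(n), variance within 2%
  big <- time_grid(1e6)
  flat <- pulse_waveform(numeric(1e6), big)
  d <- add_awgn(flat, 3, seed = 5)$samples
  expect_lt(abs(mean(d)), 4 * 3 / sqrt(1e6))
  expect_equal(stats::var(d), 9, tolerance = 0.02)
})

test_that("leading-edge trigger finds the first crossing and walks with amplitude", {
  g <- time_grid(16)
  ramp <- pulse_waveform(0:15, g)
  expect_identical(leading_edge_trigger(ramp, 2.5), 4L)  # first sample >= 2.5
  expect_true(is.na(leading_edge_trigger(ramp, 100)))
  expect_error(leading_edge_trigger(ramp, 0), "positive")

  # time-walk mechanism: a scaled-down copy of the same pulse crosses a
  # fixed threshold strictly later (dense grid, brute-force crossing)
  spec <- scintillator("GAGG")
  gd <- time_grid(20000, 0.01)
  big <- bi_exponential_pulse(spec, 511, gd)
  small <- pulse_waveform(0.25 * big$samples, gd)
  thr <- 0.05 * max(big$samples)
  expect_gt(leading_edge_trigger(small, thr), leading_edge_trigger(big, thr))
})

test_that("pure single-crystal events reproduce the analytic pulse on the window", {
  cfg <- quiet_cfg(seed = 3, energy_model = "fixed_total_fixed_fraction",
                   fraction = 1)
  ds <- generate_dataset(c("BGO", "EJ200"), 5, cfg)
  expect_true(all(ds$labels$integral[, 2] == 0))
  expect_true(all(ds$labels$amplitude[, 2] == 0))
  ref <- bi_exponential_pulse(
    scintillator("BGO"), 511, ds$grid,
    start_time = (cfg$pre_trigger_samples - 1) * ds$grid$sample_period)
  for (i in 1:5) {
    expect_equal(ds$waveforms[i, ], ref$samples, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("datasets are reproducible from a seed and differ across seeds", {
  cfg <- acquisition_config(seed = 17)
  d1 <- generate_dataset(c("LGSO", "EJ232"), 40, cfg)
  d2 <- generate_dataset(c("LGSO", "EJ232"), 40, cfg)
  expect_identical(d1$waveforms, d2$waveforms)
  expect_identical(d1$labels, d2$labels)
  d3 <- generate_dataset(c("LGSO", "EJ232"), 40, acquisition_config(seed = 18))
  expect_false(identical(d1$waveforms, d3$waveforms))
})

test_that("energy models have the documented distributions", {
  # uniform_split: E1 ~ U(0, 511), mean 255.5 within Monte-Carlo error
  cfg <- quiet_cfg(seed = 21, energy_model = "uniform_split")
  ds <- generate_dataset(c("BGO", "LGSO"), 20000, cfg)
  mc_sd <- 511 / sqrt(12) / sqrt(20000)
  expect_lt(abs(mean(ds$labels$energy_keV[, 1]) - 255.5), 4 * mc_sd)

  # fixed-total models conserve the total deposit
  cfg2 <- quiet_cfg(seed = 22)
  ds2 <- generate_dataset(c("BGO", "LGSO"), 200, cfg2)
  expect_equal(rowSums(ds2$labels$energy_keV), rep(511, 200),
               ignore_attr = TRUE)
  cfg3 <- quiet_cfg(seed = 23, energy_model = "photopeak_compton")
  ds3 <- generate_dataset(c("BGO", "LGSO"), 200, cfg3)
  expect_equal(rowSums(ds3$labels$energy_keV), rep(511, 200),
               ignore_attr = TRUE)
  expect_true(all(ds3$labels$energy_keV >= 0))
})

test_that("clean mixed integral equals the sum of per-crystal integral labels", {
  cfg <- acquisition_config(noise_sigma = 0, time_walk = TRUE,
                            trigger_threshold = 0.1, seed = 31)
  ds <- generate_dataset(c("GAGG", "EJ228"), 100, cfg)
  mixed_int <- rowSums(ds$waveforms) * ds$grid$sample_period
  expect_equal(mixed_int, rowSums(ds$labels$integral), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("trigger-aligned events place the crossing at the pre-trigger sample", {
  cfg <- acquisition_config(seed = 41)
  ds <- generate_dataset(c("BGO", "EJ200"), 60, cfg)
  pre <- cfg$pre_trigger_samples
  expect_true(all(ds$waveforms[, pre] >= ds$trigger_threshold))
  expect_true(all(ds$waveforms[, pre - 1] < ds$trigger_threshold))
})

test_that("an unreachable threshold aborts with a diagnostic", {
  cfg <- acquisition_config(trigger_threshold = 1e9, seed = 51)
  expect_error(generate_dataset(c("BGO", "EJ200"), 20, cfg),
               "failed to trigger")
})

test_that("dataset files round-trip through the text container", {
  cfg <- acquisition_config(seed = 61)
  ds <- generate_dataset(c("BGO", "EJ232"), 25, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_dataset(ds, path)
  back <- read_event_dataset(path)
  expect_equal(back$waveforms, ds$waveforms, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$labels$integral, ds$labels$integral, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$crystal_names, ds$crystal_names)
  expect_equal(back$noise_sigma, ds$noise_sigma)
  expect_equal(back$time_walk, ds$time_walk)
  expect_equal(back$pair[[2]]$tau_decay, 1.6)

  lab <- withr::local_tempfile(fileext = ".csv")
  write_labels_csv(ds, lab)
  tab <- utils::read.csv(lab)
  expect_equal(nrow(tab), 25)
  expect_equal(tab$int1, unname(ds$labels$integral[, 1]), tolerance = 1e-8)
})
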