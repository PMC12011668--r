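# Template building and matrix assembly.

test_that("identical or rescaled pulses reproduce the normalized shape", {
  g <- time_grid(512)
  p <- bi_exponential_pulse(scintillator("GAGG"), 300, g, start_time = 99)
  m <- matrix(rep(p$samples, 10), nrow = 10, byrow = TRUE)
  tpl <- build_template(m, baseline_subtract = FALSE)
  expect_equal(as.numeric(tpl), p$samples / max(p$samples), tolerance = 1e-12)
  expect_identical(attr(tpl, "n_pulses"), 10L)
  expect_equal(attr(tpl, "raw_peak"), 1)

  # amplitude-invariance: pulses at two amplitudes give the same shape
  m2 <- rbind(p$samples, 2 * p$samples, 0.5 * p$samples)
  tpl2 <- build_template(m2, baseline_subtract = FALSE)
  expect_equal(as.numeric(tpl2), as.numeric(tpl), tolerance = 1e-12)

  # idempotence: a template of copies of a template is itself
  tpl3 <- build_template(rbind(as.numeric(tpl), as.numeric(tpl)),
                         baseline_subtract = FALSE)
  expect_equal(as.numeric(tpl3), as.numeric(tpl), tolerance = 1e-12)
})

test_that("template noise shrinks with the number of averaged pulses", {
  g <- time_grid(512)
  p <- bi_exponential_pulse(scintillator("LGSO"), 400, g, start_time = 99)
  shape <- p$samples / max(p$samples)
  dev_for <- function(n, seed) {
    m <- matrix(rep(p$samples, n), nrow = n, byrow = TRUE) +
      withr::with_seed(seed, matrix(stats::rnorm(n * 512, 0, 3), n, 512))
    max(abs(as.numeric(build_template(m, baseline_subtract = FALSE)) - shape))
  }
  # 16x more pulses: max deviation should drop by roughly sqrt(16) = 4;
  # require at least a factor 2
  expect_lt(dev_for(4800, 2), dev_for(300, 1) / 2)
})

test_that("degenerate pulses are excluded with a warning, all-degenerate errors", {
  g <- time_grid(128)
  p <- bi_exponential_pulse(scintillator("EJ200"), 300, g, start_time = 20)
  m <- rbind(p$samples, numeric(128))
  expect_warning(tpl <- build_template(m, baseline_subtract = FALSE),
                 "excluded")
  expect_identical(attr(tpl, "n_pulses"), 1L)
  expect_error(
    suppressWarnings(build_template(matrix(0, 3, 128),
                                    baseline_subtract = FALSE)),
    "all pulses excluded")
})

test_that("matrix assembly validates conditioning", {
  g <- time_grid(8)
  c1 <- c(1, 0.5, 0.25, 0, 0, 0, 0, 0)
  c2 <- c(0, 0, 0, 0, 1, 0.3, 0.1, 0)
  tm <- assemble_matrix(list(c1, c2), c("a", "b"), g)
  # orthogonal columns: cond(A'A) is the ratio of squared column norms
  expect_equal(tm$condition_number,
               max(sum(c1^2), sum(c2^2)) / min(sum(c1^2), sum(c2^2)),
               tolerance = 1e-12)
  # independent eigenvalue oracle
  ev <- eigen(crossprod(cbind(c1, c2)), only.values = TRUE)$values
  expect_equal(tm$condition_number, max(ev) / min(ev), tolerance = 1e-12)

  expect_error(assemble_matrix(list(c1, c1), c("a", "b"), g),
               "indistinguishable")
  expect_error(assemble_matrix(list(c1), "a", g), "at least two")
  expect_error(assemble_matrix(list(c1, 0.7 * c2), c("a", "b"), g),
               "peak")
})

test_that("analytic templates match the closed-form normalized shape", {
  tm <- analytic_templates(c("BGO", "EJ200"), pre_trigger = 100)
  expect_lt(tm$condition_number, 1e8)
  g <- tm$grid
  for (j in 1:2) {
    sp <- scintillator(tm$crystal_names[j])
    p <- bi_exponential_pulse(sp, 511, g, start_time = 99)
    expect_equal(tm$profiles[, j], p$samples / max(p$samples),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("trigger time-walk smears the averaged profile peak below one", {
  cfg_walk <- acquisition_config(seed = 71)
  cfg_ideal <- quiet_cfg(seed = 71)
  ps_walk <- simulate_single_crystal_pulses("EJ232", 600, cfg_walk)
  ps_ideal <- simulate_single_crystal_pulses("EJ232", 600, cfg_ideal)
  raw_walk <- attr(build_template(ps_walk), "raw_peak")
  raw_ideal <- attr(build_template(ps_ideal), "raw_peak")
  expect_lt(raw_walk, 0.97)
  expect_equal(raw_ideal, 1, tolerance = 1e-6)
})

test_that("template files round-trip through CSV", {
  tm <- analytic_templates(c("LGSO", "GAGG"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_templates(tm, path)
  back <- read_templates(path)
  expect_equal(back$profiles, tm$profiles, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$crystal_names, tm$crystal_names)
  expect_equal(back$condition_number, tm$condition_number, tolerance = 1e-6)
})
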