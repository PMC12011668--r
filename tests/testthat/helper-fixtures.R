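# Shared fixtures: small grids and quick acquisition settings so unit tests
# stay fast; the full-size study configuration lives in helper-benchmark.R.

quiet_cfg <- function(seed = 1L, ...) {
  acquisition_config(noise_sigma = 0, time_walk = FALSE, seed = seed, ...)
}

# a random non-degenerate scintillator spec
random_spec <- function(name = "rnd") {
  tr <- stats::runif(1, 0.3, 2)
  td <- tr + stats::runif(1, 0.5, 300)
  scintillator_spec(name, light_yield = stats::runif(1, 5e3, 5e4),
                    tau_decay = td, tau_rise = tr)
}

# dense grid covering >= 10 decay times, for quadrature-level checks
dense_grid_for <- function(spec, period = 0.01) {
  time_grid(ceiling(10 * spec$tau_decay / period), period)
}
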