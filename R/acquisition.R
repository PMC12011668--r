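# Acquisition simulation: mixed two-crystal events with AWGN and
# leading-edge-trigger time-walk, emulating a 1 GHz digitizer record.

#' Sum two pulses sample-wise
#'
#' A gamma-ray that deposits energy in two crystals read by one photosensor
#' produces the sum of the two bi-exponential components; the mixed pulse is
#' modelled as the sample-wise sum of the per-crystal waveforms.
#'
#' @param p1,p2 [pulse_waveform()]s on identical grids.
#' @return A [pulse_waveform()].
#' @export
mix_pulses <- function(p1, p2) {
  stopifnot(inherits(p1, "pulse_waveform"), inherits(p2, "pulse_waveform"))
  if (!same_grid(p1$grid, p2$grid)) stop("grids differ: cannot mix pulses")
  pulse_waveform(p1$samples + p2$samples, p1$grid, p1$trigger_index)
}

#' Add white Gaussian noise to a waveform
#'
#' Independent zero-mean Gaussian noise of standard deviation `sigma` is
#' added to every sample, the noise model under which the pseudo-inverse
#' solve is the maximum-likelihood unmixing.
#'
#' @param p A [pulse_waveform()].
#' @param sigma Noise standard deviation in amplitude units; `sigma >= 0`.
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched and the result is reproducible.
#' @return A [pulse_waveform()].
#' @export
add_awgn <- function(p, sigma, seed = NULL) {
  stopifnot(inherits(p, "pulse_waveform"))
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(p)
  noise <- with_seed(seed, stats::rnorm(p$grid$n_samples, 0, sigma))
  pulse_waveform(p$samples + noise, p$grid, p$trigger_index)
}

#' Leading-edge discriminator
#'
#' Returns the first sample index at or above the threshold, mimicking a
#' leading-edge trigger. Because a smaller pulse takes longer to reach a
#' fixed threshold, the trigger time depends on amplitude ("time-walk"),
#' which misaligns trigger-referenced records.
#'
#' @param p A [pulse_waveform()].
#' @param threshold Trigger level in amplitude units, `> 0`.
#' @return Integer sample index, or `NA_integer_` if never crossed (a
#'   reported outcome, not an error: such events are discarded upstream).
#' @export
leading_edge_trigger <- function(p, threshold) {
  stopifnot(inherits(p, "pulse_waveform"))
  if (!is.finite(threshold) || threshold <= 0) {
    stop("threshold must be positive")
  }
  idx <- which(p$samples >= threshold)
  if (length(idx) == 0L) NA_integer_ else idx[1L]
}

#' Acquisition configuration
#'
#' Parameters of the synthetic acquisition. The noise level is expressed as
#' a fraction of the peak amplitude of a full 511 keV deposit in the first
#' crystal of the pair (default 1%); the trigger threshold defaults to five
#' times the noise standard deviation, i.e. just above the electrical noise
#' floor. Lowering the threshold reduces time-walk.
#'
#' @param noise_fraction Noise sigma as a fraction of the first crystal's
#'   full-deposit (`total_energy_keV`) peak amplitude. Ignored when
#'   `noise_sigma` is given.
#' @param noise_sigma Absolute noise sigma in amplitude units, or `NULL`.
#' @param trigger_threshold Absolute trigger level, or `NULL` for
#'   `5 * noise_sigma`.
#' @param pre_trigger_samples Samples recorded before the trigger position
#'   in the output window (default 100).
#' @param energy_model How per-event deposits are drawn:
#'   `"fixed_total_uniform_fraction"` (default; `E1 = f * E_total` with
#'   `f ~ U(0, 1)`, `E2 = E_total - E1`, spanning the full label plane),
#'   `"uniform_split"` (`E1`, `E2` independent `U(0, E_total)`),
#'   `"fixed_total_fixed_fraction"` (deterministic split by `fraction`), or
#'   `"photopeak_compton"` (single Compton scatter in crystal 1 at a
#'   uniform scattering angle, remainder absorbed in crystal 2).
#' @param total_energy_keV Total deposited energy (default 511).
#' @param fraction Crystal-1 fraction for the fixed-fraction model.
#' @param time_walk Logical; when `TRUE` records are aligned at the
#'   leading-edge trigger on the noisy summed pulse (with a random
#'   sub-sample digitizer clock phase per event), when `FALSE` records are
#'   aligned exactly at the interaction time.
#' @param seed Integer seed for the whole dataset.
#' @return An object of class `"acquisition_config"`.
#' @export
acquisition_config <- function(noise_fraction = 0.01, noise_sigma = NULL,
                               trigger_threshold = NULL,
                               pre_trigger_samples = 100L,
                               energy_model = c("fixed_total_uniform_fraction",
                                                "uniform_split",
                                                "fixed_total_fixed_fraction",
                                                "photopeak_compton"),
                               total_energy_keV = 511,
                               fraction = 0.5,
                               time_walk = TRUE,
                               seed = NULL) {
  energy_model <- match.arg(energy_model)
  if (!is.null(noise_sigma) && (!is.finite(noise_sigma) || noise_sigma < 0)) {
    stop("noise_sigma must be >= 0")
  }
  if (is.null(noise_sigma) &&
      (!is.finite(noise_fraction) || noise_fraction < 0)) {
    stop("noise_fraction must be >= 0")
  }
  if (!is.null(trigger_threshold) &&
      (!is.finite(trigger_threshold) || trigger_threshold <= 0)) {
    stop("trigger_threshold must be positive")
  }
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  structure(list(noise_fraction = noise_fraction, noise_sigma = noise_sigma,
                 trigger_threshold = trigger_threshold,
                 pre_trigger_samples = as.integer(pre_trigger_samples),
                 energy_model = energy_model,
                 total_energy_keV = total_energy_keV,
                 fraction = fraction,
                 time_walk = isTRUE(time_walk),
                 seed = seed),
            class = "acquisition_config")
}

# Resolve a pair given as character names or scintillator_spec objects.
resolve_pair <- function(pair) {
  if (is.character(pair)) {
    stopifnot(length(pair) == 2L)
    lib <- scintillator_library()
    pair <- list(scintillator(pair[1L], lib), scintillator(pair[2L], lib))
  }
  stopifnot(length(pair) == 2L,
            inherits(pair[[1L]], "scintillator_spec"),
            inherits(pair[[2L]], "scintillator_spec"))
  pair
}

# Resolve absolute noise sigma / threshold for a pair.
resolve_noise <- function(cfg, spec1) {
  sigma <- if (!is.null(cfg$noise_sigma)) cfg$noise_sigma else
    cfg$noise_fraction * pulse_peak_amplitude(spec1, cfg$total_energy_keV)
  threshold <- if (!is.null(cfg$trigger_threshold)) cfg$trigger_threshold
  else 5 * sigma
  list(sigma = sigma, threshold = threshold)
}

# Vectorized synthesis of one crystal's clean component for n events on a
# padded record. Onset of event e is at continuous sample position
# u0 + phi[e] (0-based sample units); padded sample i sits at position i-1.
# Writing j = (i-1) - u0, samples with j >= 1 carry
#   C * E * (exp(phi*T/tau_d) * exp(-j*T/tau_d) - same with tau_r),
# which factors into two rank-1 outer products; phi < 1 keeps the
# exp(phi*T/tau) factors bounded.
synth_component <- function(spec, energy_kev, phi, u0, npad, period) {
  n <- length(energy_kev)
  jmax <- npad - 1L - u0
  stopifnot(jmax >= 1L)
  cc <- (energy_kev / 1000) * spec$light_yield /
    (spec$tau_decay - spec$tau_rise)
  j <- seq_len(jmax)
  ed <- exp(-j * period / spec$tau_decay)
  er <- exp(-j * period / spec$tau_rise)
  ad <- cc * exp(phi * period / spec$tau_decay)
  ar <- cc * exp(phi * period / spec$tau_rise)
  m <- matrix(0, n, npad)
  m[, (u0 + 2L):npad] <- tcrossprod(ad, ed) - tcrossprod(ar, er)
  m
}

draw_energies <- function(cfg, n) {
  tot <- cfg$total_energy_keV
  switch(cfg$energy_model,
         fixed_total_uniform_fraction = {
           f <- stats::runif(n)
           cbind(f * tot, (1 - f) * tot)
         },
         uniform_split = cbind(stats::runif(n, 0, tot),
                               stats::runif(n, 0, tot)),
         fixed_total_fixed_fraction = cbind(rep(cfg$fraction * tot, n),
                                            rep((1 - cfg$fraction) * tot, n)),
         photopeak_compton = {
           theta <- stats::runif(n, 0, pi)
           alpha <- tot / 511
           e1 <- tot * (1 - 1 / (1 + alpha * (1 - cos(theta))))
           cbind(e1, tot - e1)
         })
}

row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, "first"))]

#' Generate a dataset of mixed two-crystal events
#'
#' For each event, per-crystal energies are drawn from the configured energy
#' model, both clean bi-exponential components are synthesized at a common
#' interaction time, summed, and white Gaussian noise is added. With
#' `time_walk = TRUE` the interaction time carries a random sub-sample
#' digitizer clock phase, the noisy sum is passed through the leading-edge
#' discriminator, and the 1024-sample output window is cut so the trigger
#' lands at `pre_trigger_samples`; events that never cross threshold (or
#' trigger too late for a full window) are redrawn and counted. Ground-truth
#' labels — per-crystal time integral, peak amplitude and energy in keV —
#' are computed from the noise-free components on the same output window.
#'
#' @param pair Two crystal names (character) or [scintillator_spec()]s;
#'   noise scaling references the first crystal.
#' @param n_events Number of events, `>= 1`.
#' @param cfg An [acquisition_config()].
#' @param grid Output record layout, default 1024 samples at 1 ns.
#' @return An object of class `"mixed_event_dataset"`: list with `waveforms`
#'   (`n_events x n_samples` matrix), `labels` (list of `integral`,
#'   `amplitude`, `energy_keV`, each `n_events x 2`), the resolved pair,
#'   grid, noise sigma, trigger threshold, seed and redraw count.
#' @export
#' @examples
#' ds <- generate_dataset(c("BGO", "EJ200"), 100,
#'                        acquisition_config(seed = 1))
#' ds
generate_dataset <- function(pair, n_events, cfg = acquisition_config(),
                             grid = time_grid()) {
  pair <- resolve_pair(pair)
  stopifnot(inherits(cfg, "acquisition_config"), n_events >= 1)
  n_events <- as.integer(n_events)
  ns <- resolve_noise(cfg, pair[[1L]])
  pre <- cfg$pre_trigger_samples
  if (pre < 10L || pre > grid$n_samples %/% 2L) {
    stop("pre_trigger_samples must be in [10, n_samples/2]")
  }
  with_seed(cfg$seed, {
    u0 <- pre + 32L
    npad <- grid$n_samples + 64L
    period <- grid$sample_period

    synth_batch <- function(m) {
      e <- draw_energies(cfg, m)
      phi <- if (cfg$time_walk) stats::runif(m) else numeric(m)
      c1 <- synth_component(pair[[1L]], e[, 1L], phi, u0, npad, period)
      c2 <- synth_component(pair[[2L]], e[, 2L], phi, u0, npad, period)
      noisy <- c1 + c2
      if (ns$sigma > 0) noisy <- noisy + matrix(
        stats::rnorm(m * npad, 0, ns$sigma), m, npad)
      list(e = e, c1 = c1, c2 = c2, noisy = noisy)
    }

    b <- synth_batch(n_events)
    if (cfg$time_walk) {
      k <- max.col(b$noisy >= ns$threshold, ties.method = "first")
      ok <- rowSums(b$noisy >= ns$threshold) > 0 &
        k - pre + 1L >= 1L & k + grid$n_samples - pre <= npad
      n_redrawn <- sum(!ok)
      if (n_redrawn > n_events / 2) {
        stop(sprintf(paste0("%d of %d events failed to trigger: threshold ",
                            "%.3g is too high for this configuration"),
                     n_redrawn, n_events, ns$threshold))
      }
      rounds <- 0L
      while (any(!ok)) {
        rounds <- rounds + 1L
        if (rounds > 50L) stop("trigger redraw did not converge")
        bad <- which(!ok)
        nb <- synth_batch(length(bad))
        kb <- max.col(nb$noisy >= ns$threshold, ties.method = "first")
        okb <- rowSums(nb$noisy >= ns$threshold) > 0 &
          kb - pre + 1L >= 1L & kb + grid$n_samples - pre <= npad
        n_redrawn <- n_redrawn + sum(!okb)
        b$e[bad, ] <- nb$e
        b$c1[bad, ] <- nb$c1
        b$c2[bad, ] <- nb$c2
        b$noisy[bad, ] <- nb$noisy
        k[bad] <- kb
        ok[bad] <- okb
      }
      start <- k - pre + 1L
    } else {
      n_redrawn <- 0L
      start <- rep.int(u0 + 2L - pre, n_events)
    }

    # Window extraction, grouped by shift (few distinct trigger positions).
    take <- function(m) {
      out <- matrix(0, n_events, grid$n_samples)
      for (s in unique(start)) {
        rows <- which(start == s)
        out[rows, ] <- m[rows, s:(s + grid$n_samples - 1L), drop = FALSE]
      }
      out
    }
    w1 <- take(b$c1); w2 <- take(b$c2); wy <- take(b$noisy)

    labels <- list(
      integral = cbind(rowSums(w1), rowSums(w2)) * period,
      amplitude = cbind(row_max(w1), row_max(w2)),
      energy_keV = b$e
    )
    colnames(labels$integral) <- colnames(labels$amplitude) <-
      colnames(labels$energy_keV) <-
      c(pair[[1L]]$name, pair[[2L]]$name)

    structure(list(waveforms = wy, labels = labels, pair = pair,
                   crystal_names = c(pair[[1L]]$name, pair[[2L]]$name),
                   grid = grid, noise_sigma = ns$sigma,
                   trigger_threshold = ns$threshold,
                   config = cfg, seed = cfg$seed,
                   time_walk = cfg$time_walk,
                   n_events = n_events, n_redrawn = n_redrawn),
              class = "mixed_event_dataset")
  })
}

#' @export
print.mixed_event_dataset <- function(x, ...) {
  cat(sprintf(paste0("<mixed_event_dataset> %d events, %s-%s, noise sigma ",
                     "%.3g, time-walk %s, seed %s\n"),
              x$n_events, x$crystal_names[1L], x$crystal_names[2L],
              x$noise_sigma, if (x$time_walk) "on" else "off",
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Subset a dataset by event index
#'
#' @param ds A `mixed_event_dataset`.
#' @param idx Integer event indices.
#' @return A `mixed_event_dataset` with the selected events.
#' @export
subset_dataset <- function(ds, idx) {
  stopifnot(inherits(ds, "mixed_event_dataset"))
  out <- ds
  out$waveforms <- ds$waveforms[idx, , drop = FALSE]
  out$labels <- lapply(ds$labels, function(m) m[idx, , drop = FALSE])
  out$n_events <- length(idx)
  out
}

#' Simulate trigger-aligned single-crystal pulses
#'
#' Produces the raw material for empirical template building: `n_pulses`
#' events in which the full deposit lands in one crystal, acquired with the
#' same noise, clock-phase and leading-edge-trigger treatment as mixed
#' events. Energies are drawn uniformly between 10% and 100% of
#' `cfg$total_energy_keV` so the amplitude-dependent trigger walk of a real
#' single-crystal calibration run is represented.
#'
#' @param spec A crystal name or [scintillator_spec()].
#' @param n_pulses Number of pulses.
#' @param cfg An [acquisition_config()]; noise scaling references `spec`.
#' @param grid Output record layout.
#' @return A `mixed_event_dataset` whose second-crystal labels are zero.
#' @export
simulate_single_crystal_pulses <- function(spec, n_pulses,
                                           cfg = acquisition_config(),
                                           grid = time_grid()) {
  if (is.character(spec)) spec <- scintillator(spec)
  stopifnot(inherits(spec, "scintillator_spec"))
  generate_single(spec, n_pulses, cfg, grid)
}

generate_single <- function(spec, n_pulses, cfg, grid) {
  ns <- resolve_noise(cfg, spec)
  pre <- cfg$pre_trigger_samples
  with_seed(cfg$seed, {
    u0 <- pre + 32L
    npad <- grid$n_samples + 64L
    period <- grid$sample_period
    n <- as.integer(n_pulses)

    synth_batch <- function(m) {
      e <- stats::runif(m, 0.1, 1) * cfg$total_energy_keV
      phi <- if (cfg$time_walk) stats::runif(m) else numeric(m)
      c1 <- synth_component(spec, e, phi, u0, npad, period)
      noisy <- c1
      if (ns$sigma > 0) noisy <- noisy + matrix(
        stats::rnorm(m * npad, 0, ns$sigma), m, npad)
      list(e = cbind(e, 0), c1 = c1, c2 = matrix(0, m, npad), noisy = noisy)
    }

    b <- synth_batch(n)
    if (cfg$time_walk) {
      k <- max.col(b$noisy >= ns$threshold, ties.method = "first")
      ok <- rowSums(b$noisy >= ns$threshold) > 0 &
        k - pre + 1L >= 1L & k + grid$n_samples - pre <= npad
      n_redrawn <- sum(!ok)
      if (n_redrawn > n / 2) stop("majority of single-crystal pulses failed to trigger")
      rounds <- 0L
      while (any(!ok)) {
        rounds <- rounds + 1L
        if (rounds > 50L) stop("trigger redraw did not converge")
        bad <- which(!ok)
        nb <- synth_batch(length(bad))
        kb <- max.col(nb$noisy >= ns$threshold, ties.method = "first")
        okb <- rowSums(nb$noisy >= ns$threshold) > 0 &
          kb - pre + 1L >= 1L & kb + grid$n_samples - pre <= npad
        n_redrawn <- n_redrawn + sum(!okb)
        b$e[bad, ] <- nb$e; b$c1[bad, ] <- nb$c1
        b$noisy[bad, ] <- nb$noisy
        k[bad] <- kb; ok[bad] <- okb
      }
      start <- k - pre + 1L
    } else {
      n_redrawn <- 0L
      start <- rep.int(u0 + 2L - pre, n)
    }
    take <- function(m) {
      out <- matrix(0, n, grid$n_samples)
      for (s in unique(start)) {
        rows <- which(start == s)
        out[rows, ] <- m[rows, s:(s + grid$n_samples - 1L), drop = FALSE]
      }
      out
    }
    w1 <- take(b$c1); wy <- take(b$noisy)
    labels <- list(integral = cbind(rowSums(w1) * period, 0),
                   amplitude = cbind(row_max(w1), 0),
                   energy_keV = b$e)
    structure(list(waveforms = wy, labels = labels,
                   pair = list(spec, spec),
                   crystal_names = c(spec$name, "none"),
                   grid = grid, noise_sigma = ns$sigma,
                   trigger_threshold = ns$threshold, config = cfg,
                   seed = cfg$seed, time_walk = cfg$time_walk,
                   n_events = n, n_redrawn = n_redrawn),
              class = "mixed_event_dataset")
  })
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
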