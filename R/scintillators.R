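#' Scintillator specification
#'
#' Bundle the constants that determine a scintillator's light pulse: the
#' light yield (optical photons emitted per MeV of deposited energy) and the
#' rise and decay time constants of the bi-exponential pulse model. Density
#' and peak emission wavelength are carried as informational metadata only.
#'
#' @param name Character identifier (e.g. `"BGO"`).
#' @param light_yield Light yield in photons/MeV; must be positive.
#' @param tau_decay Decay time constant in ns.
#' @param tau_rise Rise time constant in ns; must satisfy
#'   `0 < tau_rise < tau_decay`.
#' @param density Crystal density in g/cm^3 (informational).
#' @param peak_emission Peak emission wavelength in nm (informational).
#'
#' @return An object of class `"scintillator_spec"`.
#' @seealso [scintillator_library()], [bi_exponential_pulse()]
#' @export
#' @examples
#' lyso_like <- scintillator_spec("LYSOish", 30000, tau_decay = 41, tau_rise = 1)
#' lyso_like
scintillator_spec <- function(name, light_yield, tau_decay, tau_rise,
                              density = NA_real_, peak_emission = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(light_yield = light_yield, tau_decay = tau_decay,
            tau_rise = tau_rise)
  if (any(!is.finite(vals))) {
    stop("light_yield, tau_decay and tau_rise must be finite")
  }
  if (light_yield <= 0) stop("light_yield must be positive")
  if (tau_rise <= 0) stop("tau_rise must be positive")
  if (tau_decay == tau_rise) {
    stop("tau_decay == tau_rise: bi-exponential pulse model is degenerate")
  }
  if (tau_decay < tau_rise) stop("tau_decay must exceed tau_rise")
  structure(
    list(name = name, light_yield = as.numeric(light_yield),
         tau_decay = as.numeric(tau_decay), tau_rise = as.numeric(tau_rise),
         density = as.numeric(density),
         peak_emission = as.numeric(peak_emission)),
    class = "scintillator_spec"
  )
}

#' @export
print.scintillator_spec <- function(x, ...) {
  cat(sprintf(
    "<scintillator_spec> %s: LY %g ph/MeV, tau_decay %g ns, tau_rise %g ns\n",
    x$name, x$light_yield, x$tau_decay, x$tau_rise))
  invisible(x)
}

#' Built-in scintillator library
#'
#' The six scintillators used throughout the package benchmarks: three heavy,
#' dense inorganic crystals (BGO, LGSO, GAGG) and three fast plastic
#' scintillators (EJ200, EJ228, EJ232). Light yields, decay times, densities
#' and emission wavelengths are standard published characteristics of these
#' materials. Rise times are package defaults (1.0 ns for the dense crystals,
#' 0.5 ns for the plastics): vendor sheets rarely quote them, so they are
#' ordinary spec fields that a user can override — the estimators only assume
#' that templates and simulation use the same specs, never specific values.
#'
#' @param path Optional path to a CSV with columns `name, class,
#'   density_g_cm3, peak_emission_nm, light_yield_ph_per_MeV, decay_ns,
#'   rise_ns`; defaults to the table shipped with the package.
#'
#' @return Named list of [scintillator_spec()] objects, with a
#'   `"class"` attribute vector marking each entry `"dense"` or `"fast"`.
#' @export
#' @examples
#' lib <- scintillator_library()
#' lib$BGO
scintillator_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scintillators.csv",
                        package = "scintunmix", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    scintillator_spec(tab$name[i],
                      light_yield = tab$light_yield_ph_per_MeV[i],
                      tau_decay = tab$decay_ns[i],
                      tau_rise = tab$rise_ns[i],
                      density = tab$density_g_cm3[i],
                      peak_emission = tab$peak_emission_nm[i])
  })
  names(specs) <- tab$name
  attr(specs, "class_of") <- stats::setNames(tab$class, tab$name)
  specs
}

#' Look up one scintillator by name
#'
#' @param name Character name present in the library (case sensitive).
#' @param library Optionally a pre-loaded [scintillator_library()].
#' @return A [scintillator_spec()].
#' @export
scintillator <- function(name, library = scintillator_library()) {
  if (!name %in% names(library)) {
    stop(sprintf("unknown scintillator '%s'; available: %s", name,
                 paste(names(library), collapse = ", ")))
  }
  library[[name]]
}

#' Crystal pairings of the standard benchmark
#'
#' The twelve two-crystal combinations evaluated by the package benchmark:
#' the three dense-dense pairs (BGO-GAGG, BGO-LGSO, LGSO-GAGG) and the nine
#' dense-fast pairs (each dense crystal with each plastic). The dense crystal
#' is always listed first.
#'
#' @return List of length-2 character vectors of crystal names.
#' @export
benchmark_pairs <- function() {
  dense <- c("BGO", "LGSO", "GAGG")
  fast <- c("EJ200", "EJ228", "EJ232")
  pairs <- list(c("BGO", "GAGG"), c("BGO", "LGSO"), c("LGSO", "GAGG"))
  for (d in dense) for (f in fast) pairs[[length(pairs) + 1L]] <- c(d, f)
  pairs
}

#' Uniform sampling grid of a digitized record
#'
#' @param n_samples Number of samples in the record (default 1024).
#' @param sample_period Sampling period in ns (default 1, i.e. 1 GHz).
#' @param t0 Time of the first sample in ns.
#' @return An object of class `"time_grid"`.
#' @export
time_grid <- function(n_samples = 1024L, sample_period = 1, t0 = 0) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) stop("n_samples must be >= 2")
  if (!is.finite(sample_period) || sample_period <= 0) {
    stop("sample_period must be positive")
  }
  structure(list(n_samples = n_samples,
                 sample_period = as.numeric(sample_period),
                 t0 = as.numeric(t0)),
            class = "time_grid")
}

#' Sample times of a grid
#' @param grid A [time_grid()].
#' @return Numeric vector of sample times in ns.
#' @export
grid_times <- function(grid) {
  grid$t0 + (seq_len(grid$n_samples) - 1L) * grid$sample_period
}

same_grid <- function(g1, g2) {
  isTRUE(g1$n_samples == g2$n_samples) &&
    isTRUE(all.equal(g1$sample_period, g2$sample_period)) &&
    isTRUE(all.equal(g1$t0, g2$t0))
}

#' Digitized pulse waveform
#'
#' A single record: amplitude samples on a [time_grid()], optionally with the
#' sample index at which the acquisition trigger fired.
#'
#' @param samples Numeric vector of amplitudes, length `grid$n_samples`,
#'   finite values only.
#' @param grid A [time_grid()].
#' @param trigger_index Integer sample index of the trigger, or `NULL`.
#' @return An object of class `"pulse_waveform"`.
#' @export
pulse_waveform <- function(samples, grid, trigger_index = NULL) {
  if (length(samples) != grid$n_samples) {
    stop("length(samples) must equal grid$n_samples")
  }
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), grid = grid,
                 trigger_index = trigger_index),
            class = "pulse_waveform")
}

#' @export
print.pulse_waveform <- function(x, ...) {
  cat(sprintf("<pulse_waveform> %d samples @ %g ns, peak %.4g%s\n",
              x$grid$n_samples, x$grid$sample_period, max(x$samples),
              if (is.null(x$trigger_index)) ""
              else sprintf(", trigger @ %d", x$trigger_index)))
  invisible(x)
}
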