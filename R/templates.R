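# Peak-normalized pulse-profile templates: the columns of the matrix A
# against which the pseudo-inverse unmixing is solved.

#' Build one normalized pulse-profile column
#'
#' Each pulse is (optionally) baseline-subtracted using the mean of its
#' pre-trigger samples, divided by its own peak amplitude, and the pulses are
#' then averaged sample-wise; the average is re-normalized so its peak equals
#' one. When the input pulses carry trigger time-walk, the average of
#' individually-normalized pulses is smeared and peaks below one before
#' re-normalization; that raw peak is kept as the `"raw_peak"` attribute as a
#' diagnostic of the misalignment.
#'
#' @param pulses Either an `n_pulses x n_samples` matrix (rows = pulses), a
#'   `mixed_event_dataset` (its waveforms are used), or a list of
#'   [pulse_waveform()]s on a common grid.
#' @param baseline_subtract Subtract the per-pulse pre-trigger mean before
#'   normalizing (default `TRUE`).
#' @param baseline_samples Number of leading samples treated as baseline;
#'   default 80% of `pre_trigger`.
#' @param pre_trigger Trigger position within the record (default 100).
#' @return Numeric profile of length `n_samples`, peak exactly 1, with
#'   attributes `n_pulses` (pulses averaged) and `raw_peak`.
#' @export
build_template <- function(pulses, baseline_subtract = TRUE,
                           pre_trigger = 100L,
                           baseline_samples = floor(0.8 * pre_trigger)) {
  m <- as_pulse_matrix(pulses)
  if (nrow(m) < 1L) stop("at least one pulse is required")
  if (baseline_subtract) {
    if (baseline_samples < 1L || baseline_samples >= ncol(m)) {
      stop("baseline_samples out of range")
    }
    m <- m - rowMeans(m[, seq_len(baseline_samples), drop = FALSE])
  }
  peaks <- row_max(m)
  bad <- peaks <= 0
  if (any(bad)) {
    warning(sprintf("%d pulse(s) with non-positive peak excluded", sum(bad)))
    m <- m[!bad, , drop = FALSE]
    peaks <- peaks[!bad]
  }
  if (nrow(m) == 0L) stop("all pulses excluded: no positive-peak pulse")
  prof <- colMeans(m / peaks)
  raw_peak <- max(prof)
  prof <- prof / raw_peak
  structure(prof, n_pulses = nrow(m), raw_peak = raw_peak)
}

as_pulse_matrix <- function(pulses) {
  if (is.matrix(pulses)) return(pulses)
  if (inherits(pulses, "mixed_event_dataset")) return(pulses$waveforms)
  if (is.list(pulses) && all(vapply(pulses, inherits, TRUE, "pulse_waveform"))) {
    g <- pulses[[1L]]$grid
    if (!all(vapply(pulses, function(p) same_grid(p$grid, g), TRUE))) {
      stop("pulses must share one grid")
    }
    return(do.call(rbind, lapply(pulses, `[[`, "samples")))
  }
  stop("pulses must be a matrix, a dataset, or a list of pulse_waveform")
}

#' Assemble the template matrix A
#'
#' Stack per-crystal profile columns into the `n_samples x K` matrix used by
#' the pseudo-inverse solve. The condition number of `A'A` is computed and
#' stored; near-identical columns (crystals whose pulse shapes cannot be
#' told apart) are rejected.
#'
#' @param columns List of profile columns (as from [build_template()]), or a
#'   matrix with one column per crystal.
#' @param crystal_names Character vector naming the columns.
#' @param grid The [time_grid()] the profiles live on.
#' @param cond_cap Maximum accepted condition number of `A'A` (default 1e8).
#' @return An object of class `"template_matrix"` with fields `profiles`,
#'   `crystal_names`, `n_pulses_averaged`, `grid`, `condition_number`.
#' @export
assemble_matrix <- function(columns, crystal_names, grid = time_grid(),
                            cond_cap = 1e8) {
  if (is.matrix(columns)) {
    columns <- lapply(seq_len(ncol(columns)), function(j) columns[, j])
  }
  k <- length(columns)
  if (k < 2L) stop("at least two profile columns are required")
  lens <- vapply(columns, length, 1L)
  if (any(lens != grid$n_samples)) {
    stop("all columns must have length grid$n_samples")
  }
  if (missing(crystal_names)) crystal_names <- paste0("crystal", seq_len(k))
  stopifnot(length(crystal_names) == k)
  a <- do.call(cbind, lapply(columns, as.numeric))
  colnames(a) <- crystal_names
  peaks <- apply(a, 2L, max)
  if (any(abs(peaks - 1) > 1e-9)) {
    stop("each column's peak must equal 1 (peak-normalized profiles)")
  }
  ata <- crossprod(a)
  ev <- eigen(ata, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || !all(is.finite(ev))) {
    stop("crystals indistinguishable: A'A is singular")
  }
  cond <- max(ev) / min(ev)
  if (cond > cond_cap) {
    stop(sprintf(
      "crystals indistinguishable: condition number of A'A is %.3g (cap %.3g)",
      cond, cond_cap))
  }
  structure(list(profiles = a, crystal_names = crystal_names,
                 n_pulses_averaged = vapply(columns, function(x) {
                   np <- attr(x, "n_pulses"); if (is.null(np)) NA_integer_
                   else as.integer(np)
                 }, 1L),
                 grid = grid, condition_number = cond),
            class = "template_matrix")
}

#' @export
print.template_matrix <- function(x, ...) {
  cat(sprintf("<template_matrix> %d x %d [%s], cond(A'A) = %.3g\n",
              nrow(x$profiles), ncol(x$profiles),
              paste(x$crystal_names, collapse = ", "), x$condition_number))
  invisible(x)
}

#' Analytic template matrix for a crystal pair
#'
#' Noise-free, jitter-free templates: each column is the bi-exponential
#' pulse shape of one crystal with onset at the pre-trigger position,
#' peak-normalized. This is the idealized reference against which empirical
#' (acquisition-smeared) templates can be compared.
#'
#' @param pair Two crystal names or [scintillator_spec()]s.
#' @param grid Record layout.
#' @param pre_trigger Onset position in samples (default 100).
#' @return A `"template_matrix"`.
#' @export
analytic_templates <- function(pair, grid = time_grid(), pre_trigger = 100L) {
  pair <- resolve_pair(pair)
  cols <- lapply(pair, function(sp) {
    p <- bi_exponential_pulse(sp, 511, grid,
                              start_time = grid$t0 +
                                (pre_trigger - 1L) * grid$sample_period)
    prof <- p$samples / max(p$samples)
    structure(prof, n_pulses = 1L, raw_peak = 1)
  })
  assemble_matrix(cols, vapply(pair, `[[`, "", "name"), grid)
}

#' Empirical template matrix from simulated single-crystal runs
#'
#' Mirrors the calibration a real system would do: acquire `n_pulses`
#' trigger-aligned single-crystal pulses per crystal under the given
#' acquisition settings (noise, clock phase, leading-edge trigger) and
#' average their peak-normalized waveforms. With time-walk enabled the
#' resulting profiles carry the acquisition's misalignment smear.
#'
#' @param pair Two crystal names or [scintillator_spec()]s.
#' @param cfg An [acquisition_config()]; `cfg$seed` seeds the runs (the
#'   second crystal uses `seed + 1`).
#' @param n_pulses Pulses averaged per crystal (default 5000).
#' @param grid Record layout.
#' @param baseline_subtract Passed to [build_template()].
#' @return A `"template_matrix"`.
#' @export
empirical_templates <- function(pair, cfg = acquisition_config(),
                                n_pulses = 5000L, grid = time_grid(),
                                baseline_subtract = TRUE) {
  pair <- resolve_pair(pair)
  # one set of electronics: noise and threshold are those of the mixed-event
  # acquisition (referenced to the first crystal), not per-crystal values
  ns <- resolve_noise(cfg, pair[[1L]])
  cols <- lapply(seq_along(pair), function(i) {
    cfg_i <- cfg
    cfg_i$noise_sigma <- ns$sigma
    cfg_i$trigger_threshold <- ns$threshold
    if (!is.null(cfg$seed)) cfg_i$seed <- cfg$seed + (i - 1L)
    ps <- simulate_single_crystal_pulses(pair[[i]], n_pulses, cfg_i, grid)
    build_template(ps, baseline_subtract = baseline_subtract,
                   pre_trigger = cfg$pre_trigger_samples)
  })
  assemble_matrix(cols, vapply(pair, `[[`, "", "name"), grid)
}

#' Write / read a template matrix as CSV
#'
#' Plain-text template exchange format: '#'-prefixed metadata header lines
#' (crystal names, pulses averaged, sample period), then a CSV table with a
#' `time_ns` column and one column per crystal.
#'
#' @param tm A `"template_matrix"`.
#' @param path Output file path.
#' @return `write_templates` returns `path` invisibly; `read_templates`
#'   returns a `"template_matrix"`.
#' @export
write_templates <- function(tm, path) {
  stopifnot(inherits(tm, "template_matrix"))
  hdr <- c("#scintunmix_templates v1",
           paste0("#crystals: ", paste(tm$crystal_names, collapse = ",")),
           paste0("#n_pulses_averaged: ",
                  paste(tm$n_pulses_averaged, collapse = ",")),
           paste0("#sample_period_ns: ", tm$grid$sample_period),
           paste0("#t0_ns: ", tm$grid$t0))
  writeLines(hdr, path)
  tab <- data.table::data.table(time_ns = grid_times(tm$grid))
  for (j in seq_along(tm$crystal_names)) {
    tab[[tm$crystal_names[j]]] <- tm$profiles[, j]
  }
  data.table::fwrite(tab, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  hdr <- readLines(path, n = 16L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    ln <- grep(paste0("^#", key, ": "), hdr, value = TRUE)
    if (length(ln) != 1L) stop(sprintf("template file lacks '%s' header", key))
    sub(paste0("^#", key, ": "), "", ln)
  }
  names_ <- strsplit(get_field("crystals"), ",")[[1L]]
  n_avg <- suppressWarnings(
    as.integer(strsplit(get_field("n_pulses_averaged"), ",")[[1L]]))
  period <- as.numeric(get_field("sample_period_ns"))
  t0 <- as.numeric(get_field("t0_ns"))
  tab <- data.table::fread(path, skip = length(hdr))
  grid <- time_grid(nrow(tab), period, t0)
  cols <- lapply(seq_along(names_), function(j) {
    structure(tab[[names_[j]]], n_pulses = n_avg[j])
  })
  assemble_matrix(cols, names_, grid)
}
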