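# Plain-text event-dataset container: '#'-prefixed metadata header, then a
# CSV table with per-event labels followed by the waveform samples.

#' Write / read an event dataset
#'
#' Self-describing text format: header lines carry the crystal specs
#' (name, light yield, decay and rise constants), record layout, noise
#' sigma, trigger threshold, seed and time-walk flag; the table holds one
#' event per row with columns `E1_keV, E2_keV, int1, int2, amp1, amp2,
#' s0001..sNNNN`.
#'
#' @param ds A `mixed_event_dataset`.
#' @param path Output file path.
#' @return `write_event_dataset` returns `path` invisibly;
#'   `read_event_dataset` a `mixed_event_dataset`.
#' @export
write_event_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "mixed_event_dataset"))
  spec_line <- function(sp) {
    paste(sp$name, sp$light_yield, sp$tau_decay, sp$tau_rise, sep = ",")
  }
  hdr <- c("#scintunmix_dataset v1",
           paste0("#crystal1: ", spec_line(ds$pair[[1L]])),
           paste0("#crystal2: ", spec_line(ds$pair[[2L]])),
           paste0("#n_samples: ", ds$grid$n_samples),
           paste0("#sample_period_ns: ", ds$grid$sample_period),
           paste0("#noise_sigma: ", format(ds$noise_sigma, digits = 17)),
           paste0("#trigger_threshold: ",
                  format(ds$trigger_threshold, digits = 17)),
           paste0("#time_walk: ", ds$time_walk),
           paste0("#pre_trigger_samples: ", ds$config$pre_trigger_samples),
           paste0("#seed: ", if (is.null(ds$seed)) "NA" else ds$seed),
           paste0("#n_redrawn: ", ds$n_redrawn))
  writeLines(hdr, path)
  wf <- ds$waveforms
  colnames(wf) <- sprintf("s%04d", seq_len(ncol(wf)))
  tab <- data.table::as.data.table(cbind(
    E1_keV = ds$labels$energy_keV[, 1L], E2_keV = ds$labels$energy_keV[, 2L],
    int1 = ds$labels$integral[, 1L], int2 = ds$labels$integral[, 2L],
    amp1 = ds$labels$amplitude[, 1L], amp2 = ds$labels$amplitude[, 2L],
    wf))
  data.table::fwrite(tab, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_event_dataset
#' @export
read_event_dataset <- function(path) {
  hdr <- readLines(path, n = 32L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    ln <- grep(paste0("^#", key, ": "), hdr, value = TRUE)
    if (length(ln) != 1L) stop(sprintf("dataset file lacks '%s' header", key))
    sub(paste0("^#", key, ": "), "", ln)
  }
  parse_spec <- function(s) {
    f <- strsplit(s, ",")[[1L]]
    scintillator_spec(f[1L], as.numeric(f[2L]), as.numeric(f[3L]),
                      as.numeric(f[4L]))
  }
  sp1 <- parse_spec(get_field("crystal1"))
  sp2 <- parse_spec(get_field("crystal2"))
  grid <- time_grid(as.integer(get_field("n_samples")),
                    as.numeric(get_field("sample_period_ns")))
  seed <- suppressWarnings(as.integer(get_field("seed")))
  tab <- data.table::fread(path, skip = length(hdr))
  wcols <- grep("^s[0-9]{4}$", names(tab), value = TRUE)
  cfg <- acquisition_config(
    noise_sigma = as.numeric(get_field("noise_sigma")),
    trigger_threshold = as.numeric(get_field("trigger_threshold")),
    pre_trigger_samples = as.integer(get_field("pre_trigger_samples")),
    time_walk = identical(get_field("time_walk"), "TRUE"),
    seed = if (is.na(seed)) NULL else seed)
  labels <- list(
    integral = cbind(tab$int1, tab$int2),
    amplitude = cbind(tab$amp1, tab$amp2),
    energy_keV = cbind(tab$E1_keV, tab$E2_keV))
  for (nm in names(labels)) colnames(labels[[nm]]) <- c(sp1$name, sp2$name)
  structure(list(waveforms = as.matrix(tab[, wcols, with = FALSE]),
                 labels = labels, pair = list(sp1, sp2),
                 crystal_names = c(sp1$name, sp2$name), grid = grid,
                 noise_sigma = cfg$noise_sigma,
                 trigger_threshold = cfg$trigger_threshold,
                 config = cfg, seed = cfg$seed, time_walk = cfg$time_walk,
                 n_events = nrow(tab),
                 n_redrawn = as.integer(get_field("n_redrawn"))),
            class = "mixed_event_dataset")
}

#' Export ground-truth labels to CSV
#'
#' Labels-only view of a dataset for quick inspection in external tools.
#'
#' @param ds A `mixed_event_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(ds, path) {
  stopifnot(inherits(ds, "mixed_event_dataset"))
  tab <- data.frame(event = seq_len(ds$n_events),
                    E1_keV = ds$labels$energy_keV[, 1L],
                    E2_keV = ds$labels$energy_keV[, 2L],
                    int1 = ds$labels$integral[, 1L],
                    int2 = ds$labels$integral[, 2L],
                    amp1 = ds$labels$amplitude[, 1L],
                    amp2 = ds$labels$amplitude[, 2L])
  data.table::fwrite(tab, path)
  invisible(path)
}
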