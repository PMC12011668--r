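# Scoring and benchmark orchestration: R-squared between ground-truth and
# estimated per-crystal energy labels, per crystal / method / label type.

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` between a ground-truth series and an estimate.
#' Unbounded below; at most 1. Invariant under multiplying both series by
#' the same positive constant, but not under affine changes applied to only
#' one of them.
#'
#' @param truth Numeric vector of ground-truth values (not constant).
#' @param estimate Numeric vector of the same length (`>= 2`).
#' @return Scalar R-squared.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
r_squared <- function(truth, estimate) {
  if (length(truth) != length(estimate)) stop("lengths differ")
  if (length(truth) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(truth)) || any(!is.finite(estimate))) {
    stop("non-finite values")
  }
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("constant truth: R-squared undefined (SS_tot = 0)")
  1 - sum((truth - estimate)^2) / ss_tot
}

#' Score one estimation run
#'
#' One R-squared per crystal between the dataset's ground-truth labels of
#' the estimate's label type and the estimates, with run metadata attached.
#'
#' @param dataset The `mixed_event_dataset` the estimates refer to (use
#'   [subset_dataset()] / the validation split to score a subset).
#' @param estimates `n_events x K` estimate matrix carrying `method` and
#'   `label_type` attributes ([batch_estimate()], [predict.trained_ann()]).
#' @param method,label_type Overrides for the estimate attributes.
#' @param seed Seed recorded in the report rows.
#' @param keep_scatter If `TRUE`, attach the per-crystal (truth, estimate)
#'   pairs as the `"scatter"` attribute.
#' @return A data frame with one row per crystal: `pair`, `crystal`,
#'   `method`, `label_type`, `r_squared`, `n_events`, `noise_sigma`,
#'   `time_walk`, `seed`.
#' @export
evaluate_run <- function(dataset, estimates,
                         method = attr(estimates, "method"),
                         label_type = attr(estimates, "label_type"),
                         seed = NA_integer_, keep_scatter = FALSE) {
  stopifnot(inherits(dataset, "mixed_event_dataset"))
  if (is.null(method) || is.null(label_type)) {
    stop("method and label_type must be given or carried by the estimates")
  }
  truth <- dataset$labels[[label_type]]
  if (is.null(truth)) stop(sprintf("dataset lacks '%s' labels", label_type))
  if (nrow(estimates) != nrow(truth)) {
    stop("estimates are not aligned with the dataset events")
  }
  k <- ncol(truth)
  rows <- data.frame(
    pair = paste(dataset$crystal_names, collapse = "-"),
    crystal = dataset$crystal_names[seq_len(k)],
    method = method, label_type = label_type,
    r_squared = vapply(seq_len(k), function(j) {
      r_squared(truth[, j], estimates[, j])
    }, 1.0),
    n_events = nrow(truth),
    noise_sigma = dataset$noise_sigma,
    time_walk = dataset$time_walk,
    seed = seed,
    stringsAsFactors = FALSE
  )
  if (keep_scatter) {
    attr(rows, "scatter") <- lapply(seq_len(k), function(j) {
      data.frame(crystal = dataset$crystal_names[j],
                 truth = truth[, j], estimate = estimates[, j])
    })
  }
  rows
}

#' Benchmark estimators across crystal pairings
#'
#' Full pipeline for every (pair, seed): simulate a mixed-event dataset,
#' build empirical templates under the same acquisition settings, split
#' 4:1, then score the pseudo-inverse solve and/or the MLP on the identical
#' validation events for each label type. Templates are built once per pair
#' (a calibration measured once), with a seed derived from the pair index;
#' per-cell failures are recorded as rows with `NA` R-squared and the run
#' continues.
#'
#' @param pairs List of length-2 character vectors (default: the twelve
#'   standard pairings of [benchmark_pairs()]).
#' @param methods Subset of `c("pinv", "ann")`.
#' @param label_types Subset of `c("integral", "amplitude")`.
#' @param n_events Events per (pair, seed) dataset.
#' @param seeds Integer vector; one full run per seed.
#' @param cfg Base [acquisition_config()] (its `seed` is overridden per run).
#' @param ann An [ann_config()] (its `seed` is overridden per run).
#' @param n_template_pulses Single-crystal pulses averaged per template
#'   column (default 5000).
#' @param template_mode `"empirical"` (acquisition-smeared, default) or
#'   `"analytic"` (ideal noise-free shapes).
#' @param grid Record layout.
#' @param verbose Print one line per completed (pair, seed).
#' @return Data frame of [evaluate_run()] rows (plus an `error` column).
#' @export
benchmark_matrix <- function(pairs = benchmark_pairs(),
                             methods = c("pinv", "ann"),
                             label_types = c("integral", "amplitude"),
                             n_events = 2000L, seeds = 1:5,
                             cfg = acquisition_config(),
                             ann = ann_config(),
                             n_template_pulses = 5000L,
                             template_mode = c("empirical", "analytic"),
                             grid = time_grid(), verbose = FALSE) {
  methods <- match.arg(methods, c("pinv", "ann"), several.ok = TRUE)
  label_types <- match.arg(label_types, c("integral", "amplitude"),
                           several.ok = TRUE)
  template_mode <- match.arg(template_mode)
  out <- list()
  err_row <- function(pair, method, label_type, seed, msg) {
    data.frame(pair = paste(pair, collapse = "-"), crystal = NA_character_,
               method = method, label_type = label_type,
               r_squared = NA_real_, n_events = NA_integer_,
               noise_sigma = NA_real_, time_walk = NA, seed = seed,
               error = msg, stringsAsFactors = FALSE)
  }
  for (i in seq_along(pairs)) {
    pair <- pairs[[i]]
    tm <- tryCatch({
      if (template_mode == "analytic") {
        analytic_templates(pair, grid, cfg$pre_trigger_samples)
      } else {
        cfg_t <- cfg
        cfg_t$seed <- 900000L + i
        empirical_templates(pair, cfg_t, n_template_pulses, grid)
      }
    }, error = function(e) e)
    if (inherits(tm, "error")) {
      out[[length(out) + 1L]] <- err_row(pair, NA, NA, NA,
                                         conditionMessage(tm))
      next
    }
    for (s in seq_along(seeds)) {
      res <- tryCatch({
        dseed <- seeds[s] * 1000L + i
        cfg_d <- cfg
        cfg_d$seed <- dseed
        ds <- generate_dataset(pair, n_events, cfg_d, grid)
        sp <- split_dataset(ds, ann$train_fraction, seed = dseed + 1L)
        rows <- list()
        for (lt in label_types) {
          if ("pinv" %in% methods) {
            est <- batch_estimate(tm, sp$validation, lt)
            rows[[length(rows) + 1L]] <-
              evaluate_run(sp$validation, est, seed = seeds[s])
          }
          if ("ann" %in% methods) {
            ann_s <- ann
            ann_s$seed <- dseed + 2L
            model <- train_ann(sp$train, sp$validation, ann_s, lt)
            est <- predict(model, sp$validation)
            rows[[length(rows) + 1L]] <-
              evaluate_run(sp$validation, est, seed = seeds[s])
          }
        }
        do.call(rbind, rows)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        for (lt in label_types) for (m in methods) {
          out[[length(out) + 1L]] <-
            err_row(pair, m, lt, seeds[s], conditionMessage(res))
        }
      } else {
        res$error <- NA_character_
        out[[length(out) + 1L]] <- res
      }
      if (verbose) {
        message(sprintf("benchmark: %s seed %d done",
                        paste(pair, collapse = "-"), seeds[s]))
      }
    }
  }
  do.call(rbind, out)
}

#' Pseudo-inverse accuracy across a trigger-jitter sweep
#'
#' Scores the pseudo-inverse solve at increasing amounts of trigger
#' time-walk — alignment at the true interaction time (level `0`), then
#' leading-edge triggering at multiples of the default threshold — with
#' common seeds across levels. Raising the threshold increases the
#' amplitude-dependent crossing delay and therefore the record
#' misalignment the linear solve cannot absorb.
#'
#' By default the templates are held fixed across levels (the ideal
#' analytic shapes), which isolates the event-side mechanism: the only
#' thing that changes between levels is how the records are (mis)aligned.
#' `template_mode = "per_level"` instead recalibrates empirical templates
#' under each level's own acquisition, as a real system re-calibrated
#' after every threshold change would; that variant conflates event
#' misalignment with calibration-smear quality (the two can partially
#' compensate), so it is not guaranteed monotone.
#'
#' @param pair Two crystal names or specs.
#' @param levels Numeric threshold multipliers; `0` means time-walk off.
#' @param n_events Events per level.
#' @param cfg Base [acquisition_config()]; must carry a seed.
#' @param template_mode `"fixed"` (analytic templates at every level,
#'   default) or `"per_level"` (empirical recalibration per level).
#' @param n_template_pulses Pulses per template column (per-level mode).
#' @param label_type Label units scored.
#' @param grid Record layout.
#' @return Data frame with one row per level: `level`, `threshold`,
#'   per-crystal R-squared columns, `mean_r2`.
#' @export
time_walk_sweep <- function(pair, levels = c(0, 1, 3), n_events = 3000L,
                            cfg = acquisition_config(seed = 1L),
                            template_mode = c("fixed", "per_level"),
                            n_template_pulses = 3000L,
                            label_type = "integral",
                            grid = time_grid()) {
  pair <- resolve_pair(pair)
  template_mode <- match.arg(template_mode)
  sigma5 <- 5 * resolve_noise(cfg, pair[[1L]])$sigma
  tm_fixed <- analytic_templates(pair, grid, cfg$pre_trigger_samples)
  rows <- lapply(seq_along(levels), function(li) {
    lv <- levels[li]
    cfg_l <- cfg
    if (lv == 0) {
      cfg_l$time_walk <- FALSE
    } else {
      cfg_l$time_walk <- TRUE
      cfg_l$trigger_threshold <- lv * sigma5
    }
    tm <- if (template_mode == "fixed" || lv == 0) tm_fixed else {
      cfg_t <- cfg_l
      cfg_t$seed <- cfg$seed + 77L
      empirical_templates(pair, cfg_t, n_template_pulses, grid)
    }
    ds <- generate_dataset(pair, n_events, cfg_l, grid)
    est <- batch_estimate(tm, ds, label_type)
    ev <- evaluate_run(ds, est, seed = cfg$seed)
    data.frame(level = lv, threshold = ds$trigger_threshold,
               r2_crystal1 = ev$r_squared[1L], r2_crystal2 = ev$r_squared[2L],
               mean_r2 = mean(ev$r_squared))
  })
  do.call(rbind, rows)
}

#' Aggregate a benchmark report into a compact table
#'
#' Seed-averaged R-squared per (pair, crystal, method, label type),
#' rendered at table precision (full precision is kept in the input).
#'
#' @param report Output of [benchmark_matrix()].
#' @param digits Rounding for display (default 2).
#' @return Data frame with columns `pair`, `crystal`, `method`,
#'   `label_type`, `mean_r2` (rounded), `n_seeds`.
#' @export
summarize_report <- function(report, digits = 2L) {
  ok <- !is.na(report$r_squared)
  agg <- stats::aggregate(r_squared ~ pair + crystal + method + label_type,
                          data = report[ok, ], FUN = mean)
  cnt <- stats::aggregate(r_squared ~ pair + crystal + method + label_type,
                          data = report[ok, ], FUN = length)
  agg$n_seeds <- cnt$r_squared
  agg$mean_r2 <- round(agg$r_squared, digits)
  agg$r_squared <- NULL
  agg[order(agg$pair, agg$crystal, agg$method, agg$label_type), ]
}

#' Write a benchmark report (and optional scatter pairs) to CSV
#'
#' @param report A data frame from [benchmark_matrix()] or
#'   [evaluate_run()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  data.table::fwrite(report, path)
  invisible(path)
}
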