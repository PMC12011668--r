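# The study-scale synthetic benchmark shared by several acceptance checks:
# all twelve crystal pairings, default acquisition (time-walk on, 1% noise),
# five seeds, both estimators and both label types. 2000 events per run and
# 30 training epochs keep the full grid tractable on one CPU; computed once
# per test session on first use.

benchmark_settings <- list(
  n_events = 2000L,
  seeds = 1:5,
  ann = function() ann_config(epochs = 30L, batch_size = 256L),
  n_template_pulses = 5000L
)

.benchmark_cache <- new.env(parent = emptyenv())

full_benchmark <- function() {
  if (is.null(.benchmark_cache$report)) {
    .benchmark_cache$report <- benchmark_matrix(
      pairs = benchmark_pairs(),
      methods = c("pinv", "ann"),
      label_types = c("integral", "amplitude"),
      n_events = benchmark_settings$n_events,
      seeds = benchmark_settings$seeds,
      cfg = acquisition_config(),
      ann = benchmark_settings$ann(),
      n_template_pulses = benchmark_settings$n_template_pulses)
  }
  .benchmark_cache$report
}
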