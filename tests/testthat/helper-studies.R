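# Shared study results for the acceptance suite.  The Mueller-Brown study is
# the expensive fixture; it is computed once per test run and reused.

.study_cache <- new.env(parent = emptyenv())

mb_study <- function() {
  if (is.null(.study_cache$mb)) {
    .study_cache$mb <- suppressWarnings(
      run_mb_experiment(mb_experiment_config(seed = 2024)))
  }
  .study_cache$mb
}

dw_study <- function() {
  if (is.null(.study_cache$dw)) {
    .study_cache$dw <- suppressWarnings(
      run_doublewell_experiment(doublewell_experiment_config(seed = 2024)))
  }
  .study_cache$dw
}
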