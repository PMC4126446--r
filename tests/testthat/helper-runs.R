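# Heavy paper-scale runs shared by the acceptance criteria. Computed once
# per test session and cached; ~10 x 600-step replicates each.
.run_cache <- new.env(parent = emptyenv())

baseline_runs <- function() {
  if (is.null(.run_cache$baseline)) {
    cfg <- sim_config(run = list(n_steps = 600L, replicates = 10L, seed = 1L))
    .run_cache$baseline <- sim_run(cfg)
  }
  .run_cache$baseline
}

therapy_runs <- function(name) {
  key <- paste0("therapy_", name)
  if (is.null(.run_cache[[key]])) {
    cfg <- sim_config(run = list(n_steps = 600L, replicates = 10L, seed = 1L),
                      therapy = list(name = name))
    .run_cache[[key]] <- sim_run(cfg)
  }
  .run_cache[[key]]
}
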