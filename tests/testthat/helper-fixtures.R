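# Shared fixtures: closed-loop runs are expensive, so the three-run protocol
# for each model variant is simulated once per session and reused.

.fixture_env <- new.env(parent = emptyenv())

protocol_run <- function(variant, seed, duration_s = 30, scale = 0.2) {
  key <- paste(variant, seed, duration_s, scale, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    cfg <- stand_config(variant = variant, duration_s = duration_s,
                        scale = scale, seed = seed)
    .fixture_env[[key]] <- run_simulation(cfg)
  }
  .fixture_env[[key]]
}

protocol_runs <- function(variant, seeds = 1:3, ...) {
  lapply(seeds, function(s) protocol_run(variant, s, ...))
}

# analysis-ready (trimmed, detrended) series from a run, in mm
prep_mm <- function(x, fs = 2000) preprocess_series(x * 1000, fs, fs)

# motor-neuron unit ids of one muscle in a simulation result
.mn_ids_test <- function(result, muscle) {
  nn <- result$network$neurons
  nn$id[nn$is_mn == 1L & !is.na(nn$muscle) & nn$muscle == muscle]
}
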