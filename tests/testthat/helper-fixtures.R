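# Shared synthetic fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The default study-scale fixture (5000 genes, seed 1) and its pipeline run.
default_dataset <- function() {
  cached("default_dataset", {
    t0 <- proc.time()[["elapsed"]]
    ds <- simulate_dataset(generate_truth(generator_params(seed = 1)))
    attr(ds, "gen_seconds") <- proc.time()[["elapsed"]] - t0
    ds
  })
}

default_report <- function() {
  cached("default_report", {
    suppressMessages(run_pipeline(
      default_dataset(),
      run_config(n_random_intervals = 20000, n_resample = 500, seed = 1)
    ))
  })
}

# Zero-noise fixture and run.
noisefree_dataset <- function() {
  cached("noisefree_dataset", {
    simulate_dataset(generate_truth(
      generator_params(n_genes = 1200, seed = 11, noise = 0)
    ))
  })
}

noisefree_report <- function() {
  cached("noisefree_report", {
    suppressMessages(run_pipeline(
      noisefree_dataset(), run_config(do_enrichment = FALSE)
    ))
  })
}

# A cheap plumbing-scale fixture for I/O and pipeline-shape tests.
small_dataset <- function(seed = 5) {
  cached(paste0("small_dataset_", seed), {
    simulate_dataset(generate_truth(generator_params(
      n_genes = 250, chip_library_size = 2e5, seed = seed
    )))
  })
}
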