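# Lazily built shared fixtures (generated once per test run).

.fixture_env <- new.env()

# Full-scale synthetic input bundle at the default study conditions.
default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    dir <- file.path(tempdir(), "popnovel-default-sim")
    .fixture_env$sim <- simulate_inputs(simulation_config(seed = 20240915L), dir)
  }
  .fixture_env$sim
}

# A small, fast bundle for structural pipeline tests.
small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    dir <- file.path(tempdir(), "popnovel-small-sim")
    cfg <- simulation_config(seed = 915L, n_sites = 1200L, n_pop_sites = 600L,
                             n_pop_samples = 40L, n_exonic_known = 120L,
                             n_exonic_novel = 30L, n_per_other_class = 5L,
                             gene_model_count = 12L)
    .fixture_env$small <- simulate_inputs(cfg, dir)
  }
  .fixture_env$small
}
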