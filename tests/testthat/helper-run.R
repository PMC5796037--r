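# Shared fixtures built in code. The reference demo run (default study
# conditions, seed 42) is computed once per test session and reused by the
# pipeline, pairing and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

# small, fast cohort used by unit tests
tiny_sim_config <- function(rng_seed = 11L, ...) {
  simulation_config(n_mirna_datasets = 2L, n_mrna_datasets = 1L,
                    samples_per_group = 10L, n_mirnas = 40L, n_mrnas = 60L,
                    frac_de_mirna = 0.5, frac_de_mrna = 0.5,
                    n_planted_pairs = 5L, utr_length = 300L,
                    rng_seed = rng_seed, ...)
}

tiny_sim <- function() {
  if (is.null(.fixture_cache$tiny)) {
    cfg <- tiny_sim_config()
    sim <- simulate_cohorts(cfg)
    utr <- simulate_utrs(cfg, sim$truth)
    sim$truth$planted_sites <- utr$planted_sites
    .fixture_cache$tiny <- list(config = cfg, sim = sim, utrs = utr$utrs)
  }
  .fixture_cache$tiny
}

demo_pipeline_config <- function(seed = 42L) {
  pipeline_config(sim = simulation_config(rng_seed = seed))
}

demo_run <- function() {
  if (is.null(.fixture_cache$demo)) {
    outdir <- file.path(tempdir(), "mirpair_demo_run")
    unlink(outdir, recursive = TRUE)
    cfg <- demo_pipeline_config()
    manifest <- run_all(cfg, outdir)
    sim <- simulate_cohorts(cfg$sim)  # regenerate truth for comparison
    .fixture_cache$demo <- list(config = cfg, manifest = manifest,
                                outdir = outdir, truth = sim$truth)
  }
  .fixture_cache$demo
}
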