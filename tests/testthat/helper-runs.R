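# Shared simulated runs, cached per test session so expensive pipeline
# executions happen once.

.run_cache <- new.env(parent = emptyenv())

# Default-conditions simulated study: the parameter-recovery reference run.
default_sim_run <- function() {
  if (is.null(.run_cache$default)) {
    cfg <- pipeline_config(outdir = file.path(tempdir(), "wheatmir_default_run"),
                           rng_seed = 20140416L)
    .run_cache$default <- run_pipeline(cfg)
  }
  .run_cache$default
}

# Small, fast configuration for determinism and toggle tests.
small_sim_overrides <- function() {
  list(n_contigs = 2L, contig_length = 7000L,
       n_known_loci = 2L, n_novel_loci = 3L, n_candidate_loci = 1L,
       n_seed_specific = 1L, n_leaf_specific = 1L,
       reads_per_library = 1500L)
}

small_sim_run <- function() {
  if (is.null(.run_cache$small)) {
    cfg <- pipeline_config(outdir = file.path(tempdir(), "wheatmir_small_run"),
                           rng_seed = 7L, sim = small_sim_overrides())
    .run_cache$small <- run_pipeline(cfg)
  }
  .run_cache$small
}
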