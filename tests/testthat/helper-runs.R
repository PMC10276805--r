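# Shared end-to-end runs, computed lazily and cached for the whole session.
# The five default-condition runs are the study replicates used by the
# acceptance tests; the small run backs the cheaper explanation tests.

cf_test_cache <- new.env(parent = emptyenv())

# One replicate of the default study conditions (124 patients, 26.5%
# malignant). The generator seed and the pipeline seed both follow the
# replicate index.
default_run <- function(seed) {
  key <- paste0("default_run_", seed)
  if (is.null(cf_test_cache[[key]])) {
    cfg <- generator_config(seed = 100 + seed)
    cf_test_cache[[key]] <- run_pipeline(cfg, seed = seed)
  }
  cf_test_cache[[key]]
}

# A reduced dataset for unit-scale tests that need trained models plus the
# ability to re-render individual clusters at full resolution.
small_run <- function() {
  if (is.null(cf_test_cache$small_run)) {
    cfg <- generator_config(n_patients = 30, seed = 707)
    cf_test_cache$small_run <- list(
      config = cfg,
      run = run_pipeline(cfg, seed = 7, epochs = 8, embed_sample = 200)
    )
  }
  cf_test_cache$small_run
}

# A handful of rendered clusters from the small run's configuration.
small_clusters <- function(n = 6) {
  key <- paste0("small_clusters_", n)
  if (is.null(cf_test_cache[[key]])) {
    sr <- small_run()
    man <- sr$run$manifest
    pick <- c(head(which(man$label == "malignant"), ceiling(n / 2)),
              head(which(man$label == "benign"), floor(n / 2)))
    cf_test_cache[[key]] <- lapply(pick, function(i) {
      render_cluster(sr$config, man[i, ])
    })
  }
  cf_test_cache[[key]]
}
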