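# Heavyweight fixtures computed once per test session and shared across
# files (notably the default-configuration pipeline run used by the
# acceptance suite).

.svscape_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .svscape_cache)) {
    assign(key, builder(), envir = .svscape_cache)
  }
  get(key, envir = .svscape_cache)
}

# The stated default world: 10,000 SVs / 50 fixed differences / 3 + 26
# samples, 5+5 bulk lungs, 5 shared + 1 species-specific single-cell
# clusters. Used by recovery, clustering and enrichment acceptance tests.
default_pipeline_run <- function() {
  cache_get("default_run", function() {
    outdir <- file.path(tempdir(), "svscape_default_run")
    res <- run_pipeline(pipeline_config(seed = 1L), outdir, quiet = TRUE)
    res$outdir <- outdir
    res
  })
}

# A small cohort for merge/filter unit tests (fast, still multi-category).
small_cohort <- function() {
  cache_get("small_cohort", function() {
    cfg <- sim_config(seed = 11, n_chroms = 1, chrom_length_bp = 1e6,
                      n_genes = 50, n_sv = 250, n_divergent_sv = 5,
                      n_samples_pop_a = 3, n_samples_pop_b = 9)
    models <- make_gene_models(cfg)
    list(cfg = cfg, models = models,
         cohort = simulate_sv_cohort(models, cfg))
  })
}

# A compact two-species single-cell world for sc unit tests.
small_sc_world <- function() {
  cache_get("small_sc", function() {
    cfg <- sim_config(seed = 21, n_clusters = 3, cells_per_cluster = 80,
                      markers_per_cluster = 8)
    models <- make_gene_models(cfg)
    list(cfg = cfg, models = models,
         yak = simulate_sc_counts(models, cfg, "yak"),
         cattle = simulate_sc_counts(models, cfg, "cattle"),
         omap = make_ortholog_map(models, models, fraction_shared = 0.9,
                                  seed = 21))
  })
}
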