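#' Pipeline configuration
#'
#' Nested stage blocks whose numeric defaults are the printed parameters of
#' the analysis this package reproduces: merge distance 50 bp; site filters
#' max-missing 0.5 / mac 3 / minQ 30; Weir-Cockerham FST with top fraction
#' 0.005; promoter 2000 bp and flanks 150 bp; DE screen alpha 0.05 with
#' |log2FC| >= 1; single-cell QC min-genes 300 (population A) / 500
#' (population B) and max mito 0.20; clustering resolution 0.5 (per species)
#' and 0.1 (joint, 30 PCs); novel-cluster threshold r < 0.31.
#'
#' @param seed master seed; stage seeds derive from it.
#' @param sim a [sim_config()] describing the synthetic world.
#' @param merge,filter,fst,annotate,de,sc named lists overriding individual
#'   stage parameters (see Details in the package vignette).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = NULL,
                            merge = list(), filter = list(), fst = list(),
                            annotate = list(), de = list(), sc = list()) {
  defaults <- list(
    merge = list(max_dist_bp = 50L, require_type_match = TRUE,
                 min_support = 1L),
    filter = list(max_missing = 0.5, mac = 3L, min_qual = 30),
    fst = list(estimator = "weir_cockerham", top_fraction = 0.005),
    annotate = list(promoter_bp = 2000L, flank_bp = 150L),
    de = list(alpha = 0.05, min_abs_lfc = 1),
    sc = list(min_genes_a = 300L, min_genes_b = 500L, max_mito = 0.20,
              n_pcs = 20L, resolution = 0.5, joint_n_pcs = 30L,
              joint_resolution = 0.1, novel_r_threshold = 0.31,
              min_avg_log_fc = 1, max_p_adj = 0.05, min_pct = 0.1))
  cfg <- list(seed = as.integer(seed),
              sim = sim %||% sim_config(seed = as.integer(seed)),
              merge = utils::modifyList(defaults$merge, merge),
              filter = utils::modifyList(defaults$filter, filter),
              fst = utils::modifyList(defaults$fst, fst),
              annotate = utils::modifyList(defaults$annotate, annotate),
              de = utils::modifyList(defaults$de, de),
              sc = utils::modifyList(defaults$sc, sc))
  abort_if(cfg$fst$top_fraction <= 0 || cfg$fst$top_fraction > 1,
           "fst.top_fraction must lie in (0, 1]")
  abort_if(cfg$filter$max_missing < 0 || cfg$filter$max_missing > 1,
           "filter.max_missing must lie in [0, 1]")
  abort_if(cfg$de$alpha <= 0 || cfg$de$alpha >= 1,
           "de.alpha must lie in (0, 1)")
  abort_if(cfg$sc$max_mito < 0 || cfg$sc$max_mito > 1,
           "sc.max_mito must lie in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(quiet, ...) {
  if (!quiet) message("[svscape] ", ...)
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> merge -> filter -> FST -> top-fraction selection ->
#' region annotation -> bulk DE -> single-cell processing (per species +
#' cross-species + joint) -> gene-list integration, writing every stage
#' output plus a machine-readable run report to `outdir`. Fully reproducible
#' from the config and seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created; existing files overwritten).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with all stage objects and `report` (also
#'   written to `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         quiet = FALSE) {
  abort_if(!inherits(config, "pipeline_config"),
           "config must be a pipeline_config")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim
  t0 <- Sys.time()

  pipeline_log(quiet, "simulating gene models and SV cohort")
  models <- make_gene_models(sim)
  write_gff3(models, file.path(outdir, "genes.gff3"))
  cohort <- simulate_sv_cohort(models, sim)
  write_cohort(cohort, file.path(outdir, "cohort"))

  pipeline_log(quiet, "merging ", length(cohort$callsets), " call sets")
  merged <- merge_callsets(cohort$callsets,
                           max_dist_bp = config$merge$max_dist_bp,
                           require_type_match = config$merge$require_type_match,
                           min_support = config$merge$min_support)
  gm <- to_genotype_matrix(merged, cohort$popmap$sample)
  gm_f <- filter_callset(gm, max_missing = config$filter$max_missing,
                         mac = config$filter$mac,
                         min_qual = config$filter$min_qual)
  write_sv_vcf(gm_f, file.path(outdir, "merged_filtered.vcf"))

  pipeline_log(quiet, "FST over ", nrow(gm_f$codes), " filtered sites")
  fst <- fst_per_sv(gm_f, cohort$popmap, estimator = config$fst$estimator)
  selected <- select_top_fraction(fst, fraction = config$fst$top_fraction)
  write_fst_table(fst, gm_f, selected, file.path(outdir, "fst.tsv"))

  pipeline_log(quiet, "annotating ", nrow(gm_f$sites), " SVs")
  ann <- classify_svs(gm_f$sites, models,
                      promoter_bp = config$annotate$promoter_bp,
                      flank_bp = config$annotate$flank_bp)
  write_annotation_table(ann, file.path(outdir, "annotation.tsv"))
  lists <- gene_category_lists(ann, selected)

  pipeline_log(quiet, "bulk differential expression")
  # seed part of the DE signal inside the SV gene list so the association
  # statistics have signal to find
  de_pool <- local_seed(sim$seed + 808L, {
    n_from_sv <- min(length(lists$list1), round(0.3 * sim$n_de_genes))
    c(sample(lists$list1, n_from_sv),
      sample(setdiff(models$genes$gene_id, lists$list1),
             sim$n_de_genes - n_from_sv))
  })
  bulk <- simulate_bulk_counts(models, sim, de_gene_ids = de_pool)
  fwrite(as.data.table(bulk$counts, keep.rownames = "gene_id"),
         file.path(outdir, "bulk_counts.tsv"), sep = "\t")
  de <- de_test(bulk$counts, bulk$groups, alpha = config$de$alpha,
                min_abs_lfc = config$de$min_abs_lfc)
  fwrite(de, file.path(outdir, "de_results.tsv"), sep = "\t")
  degs <- de[is_deg == TRUE, gene_id]

  pipeline_log(quiet, "single-cell stage")
  omap <- make_ortholog_map(models, models,
                            fraction_shared = sim$fraction_shared,
                            seed = sim$seed)
  fwrite(omap, file.path(outdir, "orthologs.tsv"), sep = "\t")
  enr <- list(cluster = 1L, genes = lists$list1, fraction = 0.8)
  sc_a <- simulate_sc_counts(models, sim, sim$pop_a_label,
                             enriched_markers = enr)
  sc_b <- simulate_sc_counts(models, sim, sim$pop_b_label,
                             enriched_markers = enr)
  run_species <- function(scm, min_genes, seed_off) {
    cm <- qc_filter(scm$matrix, min_genes = min_genes,
                    max_mito = config$sc$max_mito)
    norm <- lognormalize(cm)
    labels <- cluster_cells(norm, n_pcs = config$sc$n_pcs,
                            resolution = config$sc$resolution,
                            seed = config$seed + seed_off)
    markers <- find_markers(norm, labels,
                            min_avg_log_fc = config$sc$min_avg_log_fc,
                            max_p_adj = config$sc$max_p_adj,
                            min_pct = config$sc$min_pct)
    list(cm = cm, norm = norm, labels = labels, markers = markers,
         profiles = cluster_profiles(norm, labels))
  }
  res_a <- run_species(sc_a, config$sc$min_genes_a, 11L)
  res_b <- run_species(sc_b, config$sc$min_genes_b, 12L)
  fwrite(res_a$markers, file.path(outdir, "markers_a.tsv"), sep = "\t")
  fwrite(res_b$markers, file.path(outdir, "markers_b.tsv"), sep = "\t")
  xcor <- cross_species_correlation(res_b$profiles, res_a$profiles,
                                    omap,
                                    novel_r_threshold =
                                      config$sc$novel_r_threshold)
  fwrite(as.data.table(xcor$r, keep.rownames = "cluster_b"),
         file.path(outdir, "cross_species_r.tsv"), sep = "\t")
  joint <- joint_cluster(sc_a$matrix, sc_b$matrix, omap,
                         n_pcs = config$sc$joint_n_pcs,
                         resolution = config$sc$joint_resolution,
                         seed = config$seed + 13L)
  fwrite(joint$composition, file.path(outdir, "joint_composition.tsv"),
         sep = "\t")

  pipeline_log(quiet, "integration statistics")
  universe <- unique(omap$gene_a)
  svgene <- intersect(lists$list1, universe)
  deg_u <- intersect(degs, universe)
  svdeg <- intersect(svgene, deg_u)
  assoc <- chi_square_association(universe, deg_u, svgene)
  venn <- venn_counts(lists$list1, lists$list2, degs)
  enrich <- marker_enrichment(res_a$markers,
                              list(SVgene = svgene, DEG = deg_u,
                                   SVDEG = svdeg),
                              universe)
  fwrite(enrich, file.path(outdir, "enrichment.tsv"), sep = "\t")
  jsonlite::write_json(
    list(association = assoc[c("chi2", "df", "p")],
         venn = as.list(venn)),
    file.path(outdir, "association.json"), auto_unbox = TRUE, digits = NA)

  report <- list(
    package_version = as.character(utils::packageVersion("svscape")),
    seed = config$seed,
    parameters = unclass(config)[c("merge", "filter", "fst", "annotate",
                                   "de", "sc")],
    sim = unclass(sim),
    stage_counts = list(
      svs_simulated = nrow(cohort$svs),
      merged = nrow(gm$codes), filtered = nrow(gm_f$codes),
      fst_defined = sum(!is.na(fst$fst)), high_fst = length(selected),
      list1 = length(lists$list1), list2 = length(lists$list2),
      degs = length(degs),
      cells_a = ncol(res_a$cm$counts), cells_b = ncol(res_b$cm$counts),
      clusters_a = length(unique(res_a$labels)),
      clusters_b = length(unique(res_b$labels)),
      joint_clusters = length(unique(joint$labels)),
      novel_clusters_b = xcor$novel_a))
  # timing is logged, not embedded: report.json must be bit-reproducible
  pipeline_log(quiet, sprintf("done in %.1f s",
                              as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs"))))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(models = models, cohort = cohort, merged = merged,
                 genotypes = gm_f, fst = fst, selected = selected,
                 annotation = ann, gene_lists = lists, bulk = bulk, de = de,
                 sc_a = sc_a, sc_b = sc_b, res_a = res_a, res_b = res_b,
                 cross_species = xcor, joint = joint, association = assoc,
                 venn = venn, enrichment = enrich, report = report))
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    abort_if(!startsWith(a, "--"), "unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

#' Command-line entry point
#'
#' Subcommand-per-stage CLI. `all --synthetic --out DIR [--seed N]` runs the
#' complete synthetic pipeline; `simulate`, `merge`, `filter`, `fst`,
#' `annotate` and `de` operate on files, mirroring the R API. Logs go to
#' stderr; `--quiet` silences them.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status 0 on success (invisibly); errors propagate.
#' @export
svscape_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  abort_if(length(args) == 0,
           "usage: svscape <simulate|merge|filter|fst|annotate|de|all> ",
           "[--flags]")
  cmd <- args[1]
  flags <- parse_cli_flags(args[-1])
  quiet <- isTRUE(flags$quiet)
  seed <- as.integer(flags$seed %||% 1L)
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  switch(cmd,
    all = {
      abort_if(!isTRUE(flags$synthetic),
               "only --synthetic runs are supported by 'all'")
      abort_if(is.null(flags$out), "--out DIR is required")
      run_pipeline(pipeline_config(seed = seed), flags$out, quiet = quiet)
    },
    simulate = {
      abort_if(is.null(flags$out), "--out DIR is required")
      cfg <- sim_config(seed = seed)
      models <- make_gene_models(cfg)
      dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
      write_gff3(models, file.path(flags$out, "genes.gff3"))
      write_cohort(simulate_sv_cohort(models, cfg),
                   file.path(flags$out, "cohort"))
    },
    merge = {
      abort_if(is.null(flags$vcf_dir) || is.null(flags$out),
               "--vcf_dir and --out are required")
      vcfs <- list.files(flags$vcf_dir, pattern = "\\.vcf$",
                         full.names = TRUE)
      merged <- merge_callsets(lapply(vcfs, read_sv_vcf),
                               max_dist_bp = num(flags$max_dist, 50))
      write_sv_vcf(merged, flags$out)
    },
    filter = {
      abort_if(is.null(flags$vcf) || is.null(flags$out),
               "--vcf and --out are required")
      cs <- read_sv_vcf(flags$vcf)
      gm <- genotype_matrix(cs$gt, cs$records)
      gm_f <- filter_callset(gm, max_missing = num(flags$max_missing, 0.5),
                             mac = num(flags$mac, 3),
                             min_qual = num(flags$min_qual, 30))
      write_sv_vcf(gm_f, flags$out)
    },
    fst = {
      abort_if(is.null(flags$vcf) || is.null(flags$popmap) ||
                 is.null(flags$out), "--vcf, --popmap, --out are required")
      cs <- read_sv_vcf(flags$vcf)
      gm <- genotype_matrix(cs$gt, cs$records)
      popmap <- read_population_map(flags$popmap)
      fst <- fst_per_sv(gm, popmap)
      sel <- select_top_fraction(fst, num(flags$top_fraction, 0.005))
      write_fst_table(fst, gm, sel, flags$out)
    },
    annotate = {
      abort_if(is.null(flags$vcf) || is.null(flags$gff) ||
                 is.null(flags$out), "--vcf, --gff, --out are required")
      cs <- read_sv_vcf(flags$vcf)
      models <- read_gene_models(flags$gff)
      ann <- classify_svs(cs$records, models,
                          promoter_bp = num(flags$promoter_bp, 2000),
                          flank_bp = num(flags$flank_bp, 150))
      write_annotation_table(ann, flags$out)
    },
    de = {
      abort_if(is.null(flags$counts) || is.null(flags$groups) ||
                 is.null(flags$out), "--counts, --groups, --out are required")
      tab <- fread(flags$counts)
      counts <- as.matrix(tab, rownames = 1)
      gmap <- fread(flags$groups, header = FALSE,
                    col.names = c("sample", "group"))
      groups <- factor(gmap$group[match(colnames(counts), gmap$sample)])
      fwrite(de_test(counts, groups, alpha = num(flags$alpha, 0.05),
                     min_abs_lfc = num(flags$min_abs_lfc, 1)),
             flags$out, sep = "\t")
    },
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(0L)
}
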