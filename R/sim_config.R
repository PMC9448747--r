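#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults encode the
#' cohort structure of the study system this package targets: two populations
#' of 3 and 26 diploid individuals genotyped for ~10,000 SVs of which 50 are
#' fixed differences, bulk RNA-seq of 5 vs 5 lungs, and per-species single-cell
#' matrices with 5 shared clusters plus (optionally) one species-specific
#' cluster.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_chroms,chrom_length_bp genome shape used for placement.
#' @param n_genes number of non-overlapping gene models to place.
#' @param n_samples_pop_a,n_samples_pop_b diploid cohort sizes (defaults 3/26).
#' @param n_sv total SV sites simulated.
#' @param n_divergent_sv number of SVs with a seeded allele-frequency gap.
#' @param divergence_delta `|p_A - p_B|` for divergent SVs; 1 means fixed
#'   alternate in population A and absent in B.
#' @param category_probs named probabilities over placement categories
#'   `intronic, intergenic, promoter, exonic, UTR, upstream, downstream`.
#' @param missing_rate genotype missingness rate at background (non-divergent)
#'   sites; divergent sites are modelled as confidently genotyped.
#' @param low_qual_rate fraction of background sites given sub-threshold
#'   (QUAL < 30) site quality, to exercise the quality filter.
#' @param n_bulk_a,n_bulk_b bulk RNA-seq group sizes (defaults 5/5).
#' @param n_de_genes,de_log2fc seeded differential-expression signal.
#' @param bulk_dispersion gamma-Poisson dispersion of bulk counts.
#' @param n_clusters shared single-cell clusters per species.
#' @param cells_per_cluster cells per cluster before QC failures.
#' @param markers_per_cluster seeded marker genes per cluster (disjoint sets).
#' @param mito_gene_fraction expected fraction of a healthy cell's counts
#'   carried by the reserved mitochondrial (`MT-`) genes; must be in `[0, 1)`.
#' @param species_specific_cluster logical; add one extra cluster with its own
#'   expression program to the species passed as `species_specific_in`.
#' @param species_specific_in species label receiving the extra cluster.
#' @param pop_a_label,pop_b_label population/species labels.
#' @param fraction_shared fraction of genes covered by the ortholog map.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L,
                       chrom_length_bp = 5e6,
                       n_genes = 800L,
                       n_samples_pop_a = 3L,
                       n_samples_pop_b = 26L,
                       n_sv = 10000L,
                       n_divergent_sv = 50L,
                       divergence_delta = 1,
                       category_probs = c(intronic = 0.20, intergenic = 0.55,
                                          promoter = 0.06, exonic = 0.05,
                                          UTR = 0.04, upstream = 0.05,
                                          downstream = 0.05),
                       missing_rate = 0.02,
                       low_qual_rate = 0.02,
                       n_bulk_a = 5L,
                       n_bulk_b = 5L,
                       n_de_genes = 200L,
                       de_log2fc = 2,
                       bulk_dispersion = 0.1,
                       n_clusters = 5L,
                       cells_per_cluster = 150L,
                       markers_per_cluster = 10L,
                       mito_gene_fraction = 0.05,
                       species_specific_cluster = TRUE,
                       species_specific_in = "yak",
                       pop_a_label = "cattle",
                       pop_b_label = "yak",
                       fraction_shared = 0.9) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_genes = as.integer(n_genes),
              n_samples_pop_a = as.integer(n_samples_pop_a),
              n_samples_pop_b = as.integer(n_samples_pop_b),
              n_sv = as.integer(n_sv),
              n_divergent_sv = as.integer(n_divergent_sv),
              divergence_delta = divergence_delta,
              category_probs = category_probs,
              missing_rate = missing_rate, low_qual_rate = low_qual_rate,
              n_bulk_a = as.integer(n_bulk_a), n_bulk_b = as.integer(n_bulk_b),
              n_de_genes = as.integer(n_de_genes), de_log2fc = de_log2fc,
              bulk_dispersion = bulk_dispersion,
              n_clusters = as.integer(n_clusters),
              cells_per_cluster = as.integer(cells_per_cluster),
              markers_per_cluster = as.integer(markers_per_cluster),
              mito_gene_fraction = mito_gene_fraction,
              species_specific_cluster = isTRUE(species_specific_cluster),
              species_specific_in = species_specific_in,
              pop_a_label = pop_a_label, pop_b_label = pop_b_label,
              fraction_shared = fraction_shared)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_chroms", "n_genes", "n_samples_pop_a", "n_samples_pop_b",
              "n_sv", "n_divergent_sv", "n_bulk_a", "n_bulk_b", "n_de_genes",
              "n_clusters", "cells_per_cluster", "markers_per_cluster")
  for (f in counts) abort_if(!is_count(cfg[[f]]), f, " must be a count >= 0")
  abort_if(cfg$divergence_delta < 0 || cfg$divergence_delta > 1,
           "divergence_delta must lie in [0, 1]")
  abort_if(cfg$n_divergent_sv > cfg$n_sv, "n_divergent_sv must be <= n_sv")
  abort_if(cfg$mito_gene_fraction < 0 || cfg$mito_gene_fraction >= 1,
           "mito_gene_fraction must lie in [0, 1)")
  abort_if(cfg$missing_rate < 0 || cfg$missing_rate > 1,
           "missing_rate must lie in [0, 1]")
  abort_if(cfg$fraction_shared < 0 || cfg$fraction_shared > 1,
           "fraction_shared must lie in [0, 1]")
  abort_if(abs(sum(cfg$category_probs) - 1) > 1e-8,
           "category_probs must sum to 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_sv, "SVs (", x$n_divergent_sv, "divergent, delta =",
      x$divergence_delta, ");", x$n_samples_pop_a, "+", x$n_samples_pop_b,
      "samples;", x$n_genes, "genes on", x$n_chroms, "chromosomes\n")
  invisible(x)
}
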