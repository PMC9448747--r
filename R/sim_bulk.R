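#' Simulate bulk RNA-seq counts for two groups
#'
#' Gamma-Poisson counts with gene-level dispersion and per-sample library-size
#' factors. Seeded differentially expressed genes shift the group-B mean by
#' `2^de_log2fc` with a random sign per gene.
#'
#' @param models a [gene_model_set()] supplying gene ids, or `NULL` to use
#'   synthetic ids `g00001...` (handy for calibration runs with many genes).
#' @param config a [sim_config()]; uses `n_bulk_a`, `n_bulk_b`, `n_de_genes`,
#'   `de_log2fc`, `bulk_dispersion` and, when `models` is `NULL`, `n_genes`.
#' @param de_gene_ids optional explicit set of genes to perturb (defaults to a
#'   random sample of size `n_de_genes`).
#' @return list with `counts` (genes x samples integer matrix), `groups`
#'   (factor of `pop_a_label`/`pop_b_label` per sample) and `truth`
#'   (`de` table of `gene_id, log2fc`; true `size_factors`).
#' @export
simulate_bulk_counts <- function(models, config, de_gene_ids = NULL) {
  validate_sim_config(config)
  gene_ids <- if (is.null(models) || nrow(models$genes) == 0) {
    sprintf("g%05d", seq_len(config$n_genes))
  } else {
    models$genes$gene_id
  }
  n_genes <- length(gene_ids)
  abort_if(config$n_de_genes > n_genes, "n_de_genes exceeds number of genes")
  abort_if(config$n_bulk_a < 2 || config$n_bulk_b < 2,
           "each bulk group needs >= 2 samples")
  local_seed(config$seed + 404L, {
    n_a <- config$n_bulk_a
    n_b <- config$n_bulk_b
    samples <- c(sprintf("%s_bulk%02d", config$pop_a_label, seq_len(n_a)),
                 sprintf("%s_bulk%02d", config$pop_b_label, seq_len(n_b)))
    groups <- factor(rep(c(config$pop_a_label, config$pop_b_label),
                         c(n_a, n_b)),
                     levels = c(config$pop_a_label, config$pop_b_label))
    mu <- rlnorm(n_genes, meanlog = log(200), sdlog = 1.2)
    if (is.null(de_gene_ids)) {
      de_gene_ids <- if (config$n_de_genes > 0)
        sample(gene_ids, config$n_de_genes) else character()
    } else {
      abort_if(!all(de_gene_ids %in% gene_ids),
               "de_gene_ids outside the gene universe")
    }
    sign <- sample(c(-1, 1), length(de_gene_ids), replace = TRUE)
    lfc <- setNames(rep(0, n_genes), gene_ids)
    lfc[de_gene_ids] <- sign * config$de_log2fc
    sf <- exp(rnorm(n_a + n_b, 0, 0.15))
    sf <- sf / exp(mean(log(sf)))
    disp <- config$bulk_dispersion
    counts <- matrix(0L, n_genes, n_a + n_b,
                     dimnames = list(gene_ids, samples))
    mu_mat <- matrix(mu, n_genes, n_a + n_b)
    in_b <- groups == levels(groups)[2]
    mu_mat[, in_b] <- mu_mat[, in_b] * 2^lfc
    lambda <- sweep(mu_mat, 2, sf, `*`)
    if (disp > 0) {
      lambda <- matrix(rgamma(length(lambda), shape = 1 / disp,
                              scale = disp * lambda),
                       n_genes, n_a + n_b)
    }
    counts[] <- rpois(length(lambda), lambda)
    list(counts = counts, groups = setNames(groups, samples),
         truth = list(de = data.table(gene_id = de_gene_ids,
                                      log2fc = sign * config$de_log2fc),
                      size_factors = setNames(sf, samples)))
  })
}
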