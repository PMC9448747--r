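# Bulk differential expression: the printed decision rule.
#
# Normalisation is median-of-ratios (the DESeq convention) and the call is a
# two-sided Welch t-test on log2(normalised count + 1) with the screen
# p < alpha and |log2FC| >= min_abs_lfc (the fold-change boundary is
# inclusive). No multiple-testing correction enters the call; a BH-adjusted
# column is emitted for transparency.

#' Median-of-ratios size factors
#'
#' `factor_j = median_g count_gj / geomean_g` over genes with a positive
#' geometric mean, rescaled so the factors have geometric mean 1.
#'
#' @param counts genes x samples numeric matrix.
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  geo <- exp(rowMeans(log(counts)))
  usable <- is.finite(geo) & geo > 0
  abort_if(!any(usable),
           "no gene has a nonzero count in every sample; cannot normalise")
  sf <- apply(counts, 2, function(col) median(col[usable] / geo[usable]))
  sf / exp(mean(log(sf)))
}

#' Two-group differential expression test
#'
#' Counts are divided by [size_factors()], transformed to
#' `x = log2(normalised + 1)`, and each gene is tested with a two-sided Welch
#' t-test; `log2fc = mean(x_B) - mean(x_A)` (second factor level vs first).
#' Genes with zero variance in both groups get `p = 1` when the means are
#' equal (no evidence) and `p = 0` when they differ exactly.
#'
#' @param counts genes x samples numeric matrix.
#' @param groups factor (or vector) of two levels over the samples, each with
#'   at least two members; the first level is the reference group A.
#' @param alpha significance screen (default 0.05).
#' @param min_abs_lfc inclusive fold-change screen (default 1).
#' @return data.table `gene_id, log2fc, p, p_adj_bh, is_deg` with
#'   `is_deg == (p < alpha & |log2fc| >= min_abs_lfc)`.
#' @export
de_test <- function(counts, groups, alpha = 0.05, min_abs_lfc = 1) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  abort_if(nlevels(droplevels(groups)) != 2, "exactly two groups required")
  groups <- droplevels(groups)
  in_a <- groups == levels(groups)[1]
  in_b <- groups == levels(groups)[2]
  abort_if(sum(in_a) < 2 || sum(in_b) < 2,
           "each group needs >= 2 samples")
  sf <- size_factors(counts)
  x <- log2(sweep(counts, 2, sf, `/`) + 1)
  n1 <- sum(in_a); n2 <- sum(in_b)
  m1 <- rowMeans(x[, in_a, drop = FALSE])
  m2 <- rowMeans(x[, in_b, drop = FALSE])
  v1 <- apply(x[, in_a, drop = FALSE], 1, var)
  v2 <- apply(x[, in_b, drop = FALSE], 1, var)
  se2 <- v1 / n1 + v2 / n2
  d <- m2 - m1
  t_stat <- d / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  degen <- se2 == 0
  p[degen & d == 0] <- 1
  p[degen & d != 0] <- 0
  out <- data.table(gene_id = rownames(counts) %||%
                      sprintf("g%05d", seq_len(nrow(counts))),
                    log2fc = d, p = p)
  out[, p_adj_bh := bh_adjust(p)]
  out[, is_deg := p < alpha & abs(log2fc) >= min_abs_lfc]
  out[]
}

#' Overlap of per-tissue DEG sets with an SV gene list
#'
#' @param deg_sets_by_tissue named list of character vectors (DEG ids per
#'   tissue).
#' @param sv_gene_list character vector of SV-carrying gene ids.
#' @return data.table `tissue, n_deg, n_overlap` in input order.
#' @export
overlap_counts <- function(deg_sets_by_tissue, sv_gene_list) {
  rbindlist(lapply(names(deg_sets_by_tissue), function(t) {
    degs <- unique(deg_sets_by_tissue[[t]])
    data.table(tissue = t, n_deg = length(degs),
               n_overlap = length(intersect(degs, sv_gene_list)))
  }))
}
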