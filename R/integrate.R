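# Gene-list integration statistics: the DEG-vs-SV chi-square association,
# three-list Venn regions, per-cluster marker enrichment (Fisher's exact,
# two-sided) with within-list normalised ratios, and the one-vs-rest
# membership ratio t-test.

#' Chi-square association between two gene sets over a universe
#'
#' Builds the 2x2 table of (DE yes/no) x (SV yes/no) over the gene universe
#' and applies the Pearson chi-square test with df = 1 (Yates continuity
#' correction off by default, large-count regime).
#'
#' @param universe character vector of all genes considered.
#' @param degs,sv_genes subsets of `universe`.
#' @param continuity_correction apply Yates correction (default `FALSE`).
#' @return list `chi2, df, p, table` (the 2x2 counts, DE in rows).
#' @export
chi_square_association <- function(universe, degs, sv_genes,
                                   continuity_correction = FALSE) {
  universe <- unique(universe)
  degs <- unique(degs); sv_genes <- unique(sv_genes)
  abort_if(!all(degs %in% universe), "degs must be a subset of universe")
  abort_if(!all(sv_genes %in% universe), "sv_genes must be a subset of universe")
  de <- universe %in% degs
  sv <- universe %in% sv_genes
  tab <- table(factor(de, levels = c(TRUE, FALSE)),
               factor(sv, levels = c(TRUE, FALSE)),
               dnn = c("de", "sv"))
  abort_if(any(rowSums(tab) == 0),
           "degenerate margin: DE row with zero total")
  abort_if(any(colSums(tab) == 0),
           "degenerate margin: SV column with zero total")
  ht <- stats::chisq.test(tab, correct = continuity_correction)
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, table = unclass(tab))
}

#' Seven-region Venn counts for three gene lists
#'
#' @param list1,list2,list3 character vectors (duplicates ignored).
#' @return Named integer vector over the regions `"100", "010", "001", "110",
#'   "101", "011", "111"` (digits flag membership in lists 1..3); the counts
#'   sum to the union size.
#' @export
venn_counts <- function(list1, list2, list3) {
  u <- unique(c(list1, list2, list3))
  m1 <- u %in% list1; m2 <- u %in% list2; m3 <- u %in% list3
  key <- paste0(m1 + 0L, m2 + 0L, m3 + 0L)
  regions <- c("100", "010", "001", "110", "101", "011", "111")
  out <- setNames(integer(length(regions)), regions)
  tab <- table(key)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Per-cluster gene-list enrichment among marker genes
#'
#' For each cluster's marker set `M_c` and each gene list `L`:
#' `ratio = |M_c intersect L| / |M_c|`, a two-sided Fisher's exact test on
#' the 2x2 table `[[|M_c&L|, |M_c\\L|], [|L\\M_c|, |U\\(M_c|L)|]]`, and the
#' normalised ratio (z-score of the ratio across clusters within the list,
#' `NA` when fewer than two clusters or zero variance).
#'
#' @param marker_table output of [find_markers()] (columns `cluster,
#'   gene_id`).
#' @param gene_lists named list of character vectors (e.g. `SVgene`, `DEG`,
#'   `SVDEG`), each a subset of `universe`.
#' @param universe character vector of all genes eligible as markers.
#' @return data.table `cluster, list, marker_count, overlap, ratio,
#'   normalized_ratio, fisher_odds, fisher_p`.
#' @export
marker_enrichment <- function(marker_table, gene_lists, universe) {
  universe <- unique(universe)
  mt <- as.data.table(marker_table)
  abort_if(is.null(names(gene_lists)) || any(names(gene_lists) == ""),
           "gene_lists must be named")
  for (nm in names(gene_lists)) {
    abort_if(!all(gene_lists[[nm]] %in% universe),
             "gene list '", nm, "' not a subset of universe")
  }
  markers_by_cluster <- split(mt$gene_id, mt$cluster)
  markers_by_cluster <- lapply(markers_by_cluster, function(g)
    unique(intersect(g, universe)))
  rows <- list()
  for (cl in names(markers_by_cluster)) {
    m <- markers_by_cluster[[cl]]
    if (length(m) == 0) {
      warning("cluster ", cl, " has zero markers in the universe",
              call. = FALSE)
    }
    for (nm in names(gene_lists)) {
      l <- unique(gene_lists[[nm]])
      ov <- length(intersect(m, l))
      if (length(m) > 0) {
        tab <- matrix(c(ov, length(m) - ov,
                        length(l) - ov,
                        length(universe) - length(m) - length(l) + ov),
                      2, 2, byrow = TRUE)
        ft <- fisher.test(tab, alternative = "two.sided")
        rows[[length(rows) + 1L]] <- data.table(
          cluster = cl, list = nm, marker_count = length(m), overlap = ov,
          ratio = ov / length(m), fisher_odds = unname(ft$estimate),
          fisher_p = ft$p.value)
      } else {
        rows[[length(rows) + 1L]] <- data.table(
          cluster = cl, list = nm, marker_count = 0L, overlap = 0L,
          ratio = NA_real_, fisher_odds = NA_real_, fisher_p = NA_real_)
      }
    }
  }
  out <- rbindlist(rows)
  out[, normalized_ratio := {
    v <- ratio
    if (sum(!is.na(v)) >= 2 && sd(v, na.rm = TRUE) > 0) {
      (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
    } else {
      rep(NA_real_, .N)
    }
  }, by = list]
  setcolorder(out, c("cluster", "list", "marker_count", "overlap", "ratio",
                     "normalized_ratio", "fisher_odds", "fisher_p"))
  out[]
}

#' One-vs-rest membership ratio test for a cluster
#'
#' Binary membership indicators (marker gene in `gene_list`: 1/0) over the
#' cluster's markers versus the pooled markers of all other clusters,
#' compared with a two-sided Welch t-test; the equivalent two-proportion
#' z-test is reported alongside as a cross-check.
#'
#' @param marker_table output of [find_markers()].
#' @param gene_list character vector of genes defining membership.
#' @param cluster_id the cluster to test (must have >= 2 markers; the rest
#'   pooled must also have >= 2).
#' @return list `t, df, p, z, p_z, n_cluster, n_rest, prop_cluster,
#'   prop_rest`. When all indicators are identical in both groups, `t = 0`
#'   and `p = 1`.
#' @export
one_vs_rest_ratio_test <- function(marker_table, gene_list, cluster_id) {
  mt <- as.data.table(marker_table)
  x <- as.integer(mt[cluster == cluster_id, gene_id] %in% gene_list)
  y <- as.integer(mt[cluster != cluster_id, gene_id] %in% gene_list)
  abort_if(length(x) < 2, "cluster ", cluster_id, " needs >= 2 markers")
  abort_if(length(y) < 2, "rest pool needs >= 2 markers")
  n1 <- length(x); n2 <- length(y)
  p1 <- mean(x); p2 <- mean(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    t_stat <- 0; df <- n1 + n2 - 2
    p <- if (p1 == p2) 1 else 0
    if (p1 != p2) t_stat <- Inf
  } else {
    t_stat <- (p1 - p2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(t_stat), df)
  }
  pp <- (sum(x) + sum(y)) / (n1 + n2)
  z_den <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (z_den > 0) (p1 - p2) / z_den else 0
  p_z <- if (z_den > 0) 2 * pnorm(-abs(z)) else 1
  list(t = t_stat, df = df, p = p, z = z, p_z = p_z,
       n_cluster = n1, n_rest = n2, prop_cluster = p1, prop_rest = p2)
}
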