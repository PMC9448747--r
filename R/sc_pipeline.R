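# Minimal single-cell processing: QC -> log-normalisation -> scaled PCA ->
# shared-nearest-neighbor graph -> Louvain communities -> Wilcoxon markers ->
# cross-species cluster-profile correlation. The defaults mirror the toolkit
# ecosystem the printed parameters come from: scale factor 1e4, clipping at
# +-10, k = 20 neighbours, SNN Jaccard weights pruned below 1/15.

#' Quality-control filter on cells
#'
#' Removes cells with fewer than `min_genes` detected genes (count > 0) or a
#' mitochondrial count fraction above `max_mito`. Both inequalities are
#' strict, as printed: a cell at exactly `min_genes` detected genes or exactly
#' `max_mito` mitochondrial fraction is kept. Idempotent.
#'
#' @param cm a [cell_matrix()].
#' @param min_genes minimum detected genes (species-specific in practice;
#'   e.g. 300 for one species, 500 for the other).
#' @param max_mito maximum mitochondrial fraction (default 0.20).
#' @return The filtered [cell_matrix()] with attribute `qc_stats`.
#' @export
qc_filter <- function(cm, min_genes = 300L, max_mito = 0.20) {
  abort_if(!inherits(cm, "cell_matrix"), "cm must be a cell_matrix")
  detected <- colSums(cm$counts > 0)
  totals <- colSums(cm$counts)
  mito_frac <- if (any(cm$mito)) {
    colSums(cm$counts[cm$mito, , drop = FALSE]) / pmax(totals, 1)
  } else {
    rep(0, ncol(cm$counts))
  }
  keep <- detected >= min_genes & mito_frac <= max_mito
  abort_if(!any(keep),
           "all cells removed by QC (median detected genes = ",
           median(detected), ", median mito fraction = ",
           round(median(mito_frac), 3), ")")
  out <- cell_matrix(cm$counts[, keep, drop = FALSE], mito = cm$mito,
                     species = cm$species)
  attr(out, "qc_stats") <- c(n_in = ncol(cm$counts), n_out = sum(keep),
                             fail_genes = sum(detected < min_genes),
                             fail_mito = sum(mito_frac > max_mito))
  out
}

#' Log-normalise a cell matrix
#'
#' `value = ln(1 + count / cell_total * scale)` (natural log), the global
#' scaling normalisation standard in single-cell toolkits.
#'
#' @param cm a [cell_matrix()] or bare genes x cells matrix.
#' @param scale target total per cell (default 1e4).
#' @return genes x cells numeric matrix of log-normalised values.
#' @export
lognormalize <- function(cm, scale = 1e4) {
  counts <- if (inherits(cm, "cell_matrix")) cm$counts else as.matrix(cm)
  totals <- colSums(counts)
  abort_if(any(totals == 0), "cell(s) with zero total counts; run QC first")
  log1p(sweep(counts, 2, totals, `/`) * scale)
}

scale_genes <- function(norm, clip = 10) {
  mu <- rowMeans(norm)
  sdv <- apply(norm, 1, sd)
  keep <- sdv > 0
  z <- (norm[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  pmin(pmax(z, -clip), clip)
}

snn_graph <- function(scores, k = 20L, prune = 1 / 15) {
  n <- nrow(scores)
  abort_if(n <= k, "fewer cells (", n, ") than k = ", k, " neighbours")
  d <- as.matrix(dist(scores))
  # k nearest neighbours including self
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  ind <- matrix(0, n, n)
  ind[cbind(rep(seq_len(n), k), as.vector(nn))] <- 1
  shared <- tcrossprod(ind)
  jac <- shared / (2 * k - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
}

#' Cluster cells by SNN-Louvain on principal components
#'
#' Genes are centred and scaled to unit variance (values clipped at +-10,
#' constant genes dropped), cells are embedded in the first `n_pcs` principal
#' components, a shared-nearest-neighbour graph (`k = 20`, Jaccard weights,
#' pruned below 1/15) is built, and Louvain community detection is run at the
#' given resolution under a fixed seed.
#'
#' @param norm log-normalised genes x cells matrix from [lognormalize()].
#' @param n_pcs number of principal components (default 20).
#' @param resolution Louvain resolution (default 0.5).
#' @param seed integer seed controlling the community detection.
#' @param k neighbours for the SNN graph.
#' @return Integer cluster labels (arbitrary ids) named by cell id, with the
#'   PC scores in attribute `scores`.
#' @export
cluster_cells <- function(norm, n_pcs = 20L, resolution = 0.5, seed = 0L,
                          k = 20L) {
  abort_if(ncol(norm) <= k, "fewer cells (", ncol(norm),
           ") than k = ", k, " neighbours")
  z <- scale_genes(norm)
  abort_if(nrow(z) < n_pcs,
           "need >= n_pcs (", n_pcs, ") non-constant genes, have ", nrow(z))
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  g <- snn_graph(scores, k = k)
  labels <- local_seed(seed, {
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    igraph::membership(comm)
  })
  out <- setNames(as.integer(labels), colnames(norm))
  attr(out, "scores") <- scores
  out
}

# Vectorised two-sided Wilcoxon rank-sum with tie correction and continuity
# correction, one gene per row; matches wilcox.test(exact = FALSE).
wilcox_rows <- function(ranks, tie_term, in_group) {
  n1 <- sum(in_group)
  n2 <- ncol(ranks) - n1
  n <- n1 + n2
  w <- rowSums(ranks[, in_group, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- w - mu
  correction <- sign(z) * 0.5
  sigma <- sqrt(sigma2)
  stat <- ifelse(sigma > 0, (z - correction) / sigma, 0)
  p <- 2 * pmin(pnorm(abs(stat), lower.tail = FALSE), 0.5)
  p[sigma == 0] <- 1
  p
}

#' Per-cluster marker genes (one cluster vs all other cells)
#'
#' Wilcoxon rank-sum (two-sided, normal approximation with tie and continuity
#' correction) per gene, BH adjustment across genes within each cluster,
#' `avg_log_fc` = difference of mean log-normalised expression (natural-log
#' scale). Rows are retained when `p_adj < max_p_adj`,
#' `avg_log_fc > min_avg_log_fc` (positive markers, as printed) and the
#' in-cluster detection fraction is at least `min_pct`.
#'
#' @param norm log-normalised genes x cells matrix.
#' @param labels cluster labels per cell (vector aligned with columns).
#' @param min_avg_log_fc retain markers above this natural-log fold change
#'   (default 1).
#' @param max_p_adj BH-adjusted p-value ceiling (default 0.05).
#' @param min_pct minimum detection fraction in the cluster (default 0.1).
#' @return data.table `cluster, gene_id, avg_log_fc, pct_in, pct_out, p,
#'   p_adj`, sorted by cluster then decreasing `avg_log_fc`; attribute
#'   `log_base` records the log scale. Clusters of size 1 are skipped with a
#'   warning.
#' @export
find_markers <- function(norm, labels, min_avg_log_fc = 1, max_p_adj = 0.05,
                         min_pct = 0.1) {
  labels <- as.vector(labels)
  abort_if(length(labels) != ncol(norm), "labels must match columns of norm")
  abort_if(length(unique(labels)) < 2, "need >= 2 clusters for markers")
  ranks <- t(apply(norm, 1, rank))
  tie_term <- apply(norm, 1, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
  detected <- norm > 0
  rows <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    if (sum(in_cl) < 2) {
      warning("cluster ", cl, " has a single cell; skipped", call. = FALSE)
      next
    }
    p <- wilcox_rows(ranks, tie_term, in_cl)
    p_adj <- bh_adjust(p)
    lfc <- rowMeans(norm[, in_cl, drop = FALSE]) -
      rowMeans(norm[, !in_cl, drop = FALSE])
    pct_in <- rowMeans(detected[, in_cl, drop = FALSE])
    pct_out <- rowMeans(detected[, !in_cl, drop = FALSE])
    keep <- p_adj < max_p_adj & lfc > min_avg_log_fc & pct_in >= min_pct
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <-
      data.table(cluster = cl, gene_id = rownames(norm)[keep],
                 avg_log_fc = lfc[keep], pct_in = pct_in[keep],
                 pct_out = pct_out[keep], p = p[keep], p_adj = p_adj[keep])
  }
  out <- if (length(rows)) rbindlist(rows) else
    data.table(cluster = integer(), gene_id = character(),
               avg_log_fc = numeric(), pct_in = numeric(),
               pct_out = numeric(), p = numeric(), p_adj = numeric())
  setorder(out, cluster, -avg_log_fc)
  setattr(out, "log_base", "natural")
  out[]
}

#' Mean expression profile per cluster
#'
#' @param norm log-normalised genes x cells matrix.
#' @param labels cluster labels per cell.
#' @return genes x clusters matrix of mean log-normalised expression.
#' @export
cluster_profiles <- function(norm, labels) {
  labels <- as.vector(labels)
  abort_if(length(labels) != ncol(norm), "labels must match columns of norm")
  cls <- sort(unique(labels))
  out <- vapply(cls, function(cl)
    rowMeans(norm[, labels == cl, drop = FALSE]), numeric(nrow(norm)))
  colnames(out) <- as.character(cls)
  out
}

#' Cross-species cluster correlation and novel-cluster flagging
#'
#' Pearson correlation between per-cluster mean log-normalised profiles of
#' two species, restricted to ortholog pairs. A cluster is flagged novel when
#' its best correlation with any cluster of the other species falls strictly
#' below `novel_r_threshold`; a cluster whose best r equals the threshold
#' exactly is not flagged.
#'
#' @param profiles_a,profiles_b genes x clusters profile matrices (see
#'   [cluster_profiles()]), rownames = species-own gene ids.
#' @param ortholog_map data.table `gene_a, gene_b` (or `NULL` to match by
#'   shared rownames).
#' @param novel_r_threshold novelty threshold (default 0.31, strict `<`).
#' @return list with `r` (clusters_A x clusters_B correlation matrix),
#'   `novel_a`, `novel_b` (flagged cluster names per side) and `n_orthologs`.
#' @export
cross_species_correlation <- function(profiles_a, profiles_b,
                                      ortholog_map = NULL,
                                      novel_r_threshold = 0.31) {
  if (is.null(ortholog_map)) {
    shared <- intersect(rownames(profiles_a), rownames(profiles_b))
    ortholog_map <- data.table(gene_a = shared, gene_b = shared)
  }
  om <- as.data.table(ortholog_map)
  om <- om[gene_a %in% rownames(profiles_a) & gene_b %in% rownames(profiles_b)]
  pa <- profiles_a[om$gene_a, , drop = FALSE]
  pb <- profiles_b[om$gene_b, , drop = FALSE]
  usable <- apply(pa, 1, sd) > 0 | apply(pb, 1, sd) > 0
  abort_if(sum(usable) < 2,
           "need >= 2 shared orthologs with nonzero variance, have ",
           sum(usable))
  r <- cor(pa, pb)
  novel_a <- colnames(pa)[apply(r, 1, max) < novel_r_threshold]
  novel_b <- colnames(pb)[apply(r, 2, max) < novel_r_threshold]
  list(r = r, novel_a = novel_a, novel_b = novel_b, n_orthologs = nrow(om))
}

#' Joint clustering of two species over orthologs
#'
#' A simplified stand-in for anchor-based integration adequate for data
#' without batch effects: both matrices are restricted to ortholog pairs and
#' renamed to a common namespace, log-normalised per species, concatenated,
#' gene-scaled jointly, embedded with PCA and clustered with SNN-Louvain.
#' (Scaling jointly rather than per species avoids manufacturing a batch
#' offset when one species carries a cluster the other lacks: species-wise
#' gene variances then differ systematically and per-species z-scores pull
#' homologous cells apart.)
#'
#' @param cm_a,cm_b [cell_matrix()] objects.
#' @param ortholog_map data.table `gene_a, gene_b` (non-empty).
#' @param n_pcs principal components (default 30).
#' @param resolution Louvain resolution (default 0.1).
#' @param seed integer seed.
#' @param k SNN neighbours.
#' @return list with `labels` (named integer vector over all cells),
#'   `species` (species per cell) and `composition` (data.table of
#'   per-cluster species fractions; rows sum to 1).
#' @export
joint_cluster <- function(cm_a, cm_b, ortholog_map, n_pcs = 30L,
                          resolution = 0.1, seed = 0L, k = 20L) {
  om <- as.data.table(ortholog_map)
  abort_if(nrow(om) == 0, "ortholog map is empty")
  om <- om[gene_a %in% cm_a$gene_ids & gene_b %in% cm_b$gene_ids]
  abort_if(nrow(om) == 0, "no ortholog pair present in both matrices")
  common <- om$gene_a
  prep <- function(cm, ids) {
    counts <- cm$counts[ids, , drop = FALSE]
    rownames(counts) <- common
    lognormalize(counts)
  }
  norm <- cbind(prep(cm_a, om$gene_a), prep(cm_b, om$gene_b))
  z <- scale_genes(norm)
  species <- setNames(rep(c(cm_a$species, cm_b$species),
                          c(ncol(cm_a$counts), ncol(cm_b$counts))),
                      colnames(norm))
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE, rank. = n_pcs)
  g <- snn_graph(pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE], k = k)
  labels <- local_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  labels <- setNames(as.integer(labels), colnames(z))
  comp <- data.table(cluster = labels, species = species)[
    , .(n = .N), by = .(cluster, species)][
    , frac := n / sum(n), by = cluster]
  comp_wide <- dcast(comp, cluster ~ species, value.var = "frac", fill = 0)
  list(labels = labels, species = species, composition = comp_wide[])
}
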