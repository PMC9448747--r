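toy_cells <- function(counts, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, cells)
  cell_matrix(counts, species = "toy")
}

test_that("qc_filter applies strict inequalities on both rules", {
  # 400 genes; cells engineered around the detected-gene boundary
  n_genes <- 400
  mk_cell <- function(n_detected, mito_counts = 0) {
    v <- integer(n_genes + 1)
    v[seq_len(n_detected)] <- 5L
    v[n_genes + 1] <- as.integer(mito_counts)
    v
  }
  counts <- cbind(mk_cell(300), mk_cell(299), mk_cell(250),
                  mk_cell(320, mito_counts = 400),   # mito = 0.2 exactly
                  mk_cell(320, mito_counts = 534))   # mito = 0.25
  genes <- c(sprintf("g%03d", 1:n_genes), "MT-01")
  cm <- toy_cells(counts, genes = genes)
  out <- qc_filter(cm, min_genes = 300, max_mito = 0.20)
  kept <- colnames(out$counts)
  expect_setequal(kept, c("c001", "c004"))
  # mito fraction of c004 is exactly 400/2000 = 0.2 -> kept
  expect_true("c004" %in% kept)
  # idempotence
  out2 <- qc_filter(out, min_genes = 300, max_mito = 0.20)
  expect_identical(out2$counts, out$counts)
  expect_error(qc_filter(cm, min_genes = 1000), "all cells removed")
})

test_that("lognormalize matches its closed form", {
  set.seed(10)
  counts <- matrix(rpois(200, 5), 20, 10)
  cm <- toy_cells(counts)
  norm <- lognormalize(cm)
  direct <- log(1 + sweep(counts, 2, colSums(counts), `/`) * 1e4)
  expect_equal(unname(norm), unname(direct), tolerance = 1e-12)
  expect_equal(norm[counts == 0], rep(0, sum(counts == 0)))
  # cell total equal to scale gives ln(1 + count)
  col <- matrix(c(9999L, 1L, rep(0L, 18)), 20, 1)
  cm2 <- toy_cells(col)
  expect_equal(unname(lognormalize(cm2, scale = 1e4)[1:2, 1]),
               log(1 + c(9999, 1)))
  zero <- toy_cells(matrix(0L, 5, 2))
  expect_error(lognormalize(zero), "zero total")
})

test_that("cluster_cells recovers planted structure and is deterministic", {
  w <- small_sc_world()
  cm <- qc_filter(w$cattle$matrix, min_genes = 300)
  norm <- lognormalize(cm)
  lab <- cluster_cells(norm, seed = 3)
  truth <- w$cattle$truth$labels[colnames(norm)]
  expect_gte(adjusted_rand_index(lab, truth), 0.9)
  lab2 <- cluster_cells(norm, seed = 3)
  expect_identical(as.integer(lab), as.integer(lab2))
  expect_error(cluster_cells(norm[, 1:10], seed = 1), "fewer cells")
})

test_that("a homogeneous population yields one cluster at resolution 0.5", {
  cfg <- sim_config(seed = 77, n_clusters = 1, cells_per_cluster = 150,
                    species_specific_cluster = FALSE)
  sim <- simulate_sc_counts(NULL, cfg, "cattle")
  cm <- qc_filter(sim$matrix, min_genes = 300)
  norm <- lognormalize(cm)
  lab <- cluster_cells(norm, resolution = 0.5, seed = 1)
  expect_equal(length(unique(lab)), 1)
})

test_that("find_markers recovers seeded markers and rejects shuffled labels", {
  w <- small_sc_world()
  cm <- qc_filter(w$cattle$matrix, min_genes = 300)
  norm <- lognormalize(cm)
  truth <- w$cattle$truth$labels[colnames(norm)]
  mk <- find_markers(norm, truth)
  for (cl in seq_along(w$cattle$truth$marker_assignment)) {
    seeded <- w$cattle$truth$marker_assignment[[cl]]
    found <- mk[cluster == cl, gene_id]
    expect_gte(length(intersect(seeded, found)) / length(seeded), 0.8)
    expect_gte(length(intersect(seeded, found)) / max(length(found), 1), 0.8)
  }
  # permutation null: shuffled labels produce (almost) nothing
  set.seed(5)
  mk_null <- find_markers(norm, sample(truth))
  expect_lte(nrow(mk_null),
             0.01 * nrow(norm) * length(unique(truth)))
  # a constant gene can never appear
  norm_c <- rbind(norm, constant = rep(3, ncol(norm)))
  mk_c <- find_markers(norm_c, truth)
  expect_false("constant" %in% mk_c$gene_id)
})

test_that("vectorised Wilcoxon matches wilcox.test", {
  set.seed(6)
  x <- matrix(rnorm(5 * 60), 5, 60)
  x[2, ] <- round(x[2, ])  # force ties
  grp <- rep(c(TRUE, FALSE), c(25, 35))
  ranks <- t(apply(x, 1, rank))
  ties <- apply(x, 1, function(v) { t <- table(v); sum(t^3 - t) })
  p_vec <- svscape:::wilcox_rows(ranks, ties, grp)
  for (i in 1:5) {
    p_ref <- wilcox.test(x[i, grp], x[i, !grp], exact = FALSE,
                         correct = TRUE)$p.value
    expect_equal(p_vec[i], p_ref, tolerance = 1e-10)
  }
})

test_that("marker output is invariant under cluster label permutation", {
  w <- small_sc_world()
  cm <- qc_filter(w$cattle$matrix, min_genes = 300)
  norm <- lognormalize(cm)
  truth <- w$cattle$truth$labels[colnames(norm)]
  mk <- find_markers(norm, truth)
  remap <- c(`1` = 7L, `2` = 5L, `3` = 9L)
  mk_perm <- find_markers(norm, remap[as.character(truth)])
  for (cl in names(remap)) {
    expect_setequal(mk[cluster == as.integer(cl), gene_id],
                    mk_perm[cluster == remap[[cl]], gene_id])
  }
})

test_that("cluster size 1 is skipped with a warning", {
  set.seed(8)
  norm <- matrix(rnorm(40 * 21, 5), 40, 21,
                 dimnames = list(sprintf("g%02d", 1:40),
                                 sprintf("c%02d", 1:21)))
  labels <- c(rep(1, 20), 2)
  expect_warning(find_markers(norm, labels), "single cell")
})

test_that("cross-species correlation flags novelty strictly below threshold", {
  w <- small_sc_world()
  run1 <- function(sim, mg) {
    cm <- qc_filter(sim$matrix, min_genes = mg)
    norm <- lognormalize(cm)
    truth <- sim$truth$labels[colnames(norm)]
    cluster_profiles(norm, truth)
  }
  py <- run1(w$yak, 500)
  pc <- run1(w$cattle, 300)
  x <- cross_species_correlation(py, pc, w$omap)
  novel_truth <- as.character(w$yak$truth$species_specific_cluster_id)
  expect_equal(x$novel_a, novel_truth)
  expect_length(x$novel_b, 0)
  # matched shared clusters correlate near 1
  shared <- setdiff(colnames(py), novel_truth)
  for (cl in shared) expect_gt(x$r[cl, cl], 0.9)
  # identical profiles: r = 1 on the diagonal, nothing novel
  self <- cross_species_correlation(pc, pc, NULL)
  expect_equal(unname(diag(self$r)), rep(1, ncol(pc)))
  expect_length(self$novel_a, 0)
  # strictness at the boundary: a cluster whose best r equals the threshold
  # exactly is not flagged; epsilon above the observed r, it is
  r_max <- max(x$r[novel_truth, ])
  at <- cross_species_correlation(py, pc, w$omap, novel_r_threshold = r_max)
  expect_false(novel_truth %in% at$novel_a)
  above <- cross_species_correlation(py, pc, w$omap,
                                     novel_r_threshold = r_max + 1e-12)
  expect_true(novel_truth %in% above$novel_a)
  expect_error(cross_species_correlation(py[1, , drop = FALSE],
                                         pc[1, , drop = FALSE], NULL),
               "orthologs")
})

test_that("joint clustering mixes species in shared clusters only", {
  w <- small_sc_world()
  j <- joint_cluster(w$cattle$matrix, w$yak$matrix, w$omap, seed = 9)
  comp <- j$composition
  frac_cols <- setdiff(names(comp), "cluster")
  expect_equal(rowSums(as.matrix(comp[, ..frac_cols])),
               rep(1, nrow(comp)), ignore_attr = TRUE)
  # the species-specific cluster is >= 95% yak in its joint cluster
  novel_cells <- names(w$yak$truth$labels)[
    w$yak$truth$labels == w$yak$truth$species_specific_cluster_id]
  novel_cells <- intersect(novel_cells, names(j$labels))
  novel_joint <- names(sort(table(j$labels[novel_cells]),
                            decreasing = TRUE))[1]
  expect_gte(comp[cluster == as.integer(novel_joint), yak], 0.95)
  # shared truth clusters land in mixed joint clusters
  shared_cl <- comp[cattle > 0.2 & yak > 0.2, cluster]
  expect_gte(length(shared_cl), 2)
  expect_error(joint_cluster(w$cattle$matrix, w$yak$matrix,
                             data.table::data.table(gene_a = character(),
                                                    gene_b = character())),
               "empty")
})

test_that("MTX round-trip preserves the cell matrix", {
  w <- small_sc_world()
  cm <- w$cattle$matrix
  dir <- withr::local_tempdir()
  write_cell_matrix_mtx(cm, dir)
  back <- read_cell_matrix_mtx(dir, species = "cattle")
  expect_identical(unname(back$counts), unname(cm$counts))
  expect_equal(back$gene_ids, cm$gene_ids)
  expect_equal(back$mito, cm$mito)
})
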