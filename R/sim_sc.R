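#' Cell-level count matrix container
#'
#' @param counts genes x cells non-negative integer matrix with dimnames.
#' @param mito logical per-gene mitochondrial flags; defaults to gene ids
#'   starting with `"MT-"`.
#' @param species species label attached to the matrix.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, mito = NULL, species = NA_character_) {
  counts <- as.matrix(counts)
  abort_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "counts must carry gene and cell ids as dimnames")
  abort_if(any(counts < 0) || any(counts != floor(counts)),
           "counts must be non-negative integers")
  if (is.null(mito)) mito <- startsWith(rownames(counts), "MT-")
  abort_if(length(mito) != nrow(counts), "mito flag length mismatch")
  structure(list(counts = counts, gene_ids = rownames(counts),
                 cell_ids = colnames(counts), mito = mito,
                 species = species),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix (", x$species, "): ", nrow(x$counts), " genes x ",
      ncol(x$counts), " cells, ", sum(x$mito), " mito genes\n", sep = "")
  invisible(x)
}

#' Simulate clustered single-cell counts
#'
#' Cells are Poisson draws around per-cluster mean profiles built from a
#' baseline expression program shared by all clusters, with each cluster's
#' seeded marker genes elevated by a factor `exp(2)` (comfortably above the
#' e-fold contract). Ten reserved `MT-` genes contribute on average
#' `mito_gene_fraction` of each healthy cell's counts; a small heavy-tailed
#' minority of failing cells carries 25-60% mitochondrial counts and a second
#' small slice is sequenced at very low depth, so both QC rules have work to
#' do. When `config$species_specific_cluster` is set and `species_label`
#' matches `config$species_specific_in`, one extra cluster with its own
#' independent expression program and unique markers is appended.
#'
#' @param models a [gene_model_set()] supplying the gene universe (or `NULL`
#'   for synthetic ids).
#' @param config a [sim_config()].
#' @param species_label species tag for the generated matrix; also offsets the
#'   RNG stream so the two species get independent cells.
#' @param enriched_markers optional `list(cluster = k, genes = ids,
#'   fraction = f)`: draw a fraction of cluster `k`'s markers from `genes`
#'   (used to seed a cluster whose markers overlap the high-FST gene list).
#' @return list with `matrix` (a [cell_matrix()]) and `truth` (per-cell
#'   cluster labels, `marker_assignment`, `species_specific_cluster_id` or
#'   `NULL`, mito gene ids, failing/low-depth cell ids).
#' @export
simulate_sc_counts <- function(models, config, species_label,
                               enriched_markers = NULL) {
  validate_sim_config(config)
  abort_if(config$n_clusters < 1, "n_clusters must be >= 1")
  gene_ids <- if (is.null(models) || nrow(models$genes) == 0) {
    sprintf("g%05d", seq_len(config$n_genes))
  } else {
    models$genes$gene_id
  }
  n_mito <- 10L
  mito_ids <- sprintf("MT-%02d", seq_len(n_mito))
  all_ids <- c(gene_ids, mito_ids)
  k_shared <- config$n_clusters
  abort_if(config$markers_per_cluster * k_shared > length(gene_ids),
           "markers_per_cluster x n_clusters exceeds number of genes")
  has_novel <- config$species_specific_cluster &&
    identical(species_label, config$species_specific_in)
  k_total <- k_shared + as.integer(has_novel)
  n_genes <- length(gene_ids)
  f_mito <- config$mito_gene_fraction
  # the expression "world" -- baseline program, marker sets, and the novel
  # cluster's program -- is drawn under a species-independent stream so both
  # species share cluster identities; per-species streams only add cells
  world <- local_seed(config$seed + 606L, {
    base_w <- rlnorm(n_genes, 0, 1)
    pool <- sample(gene_ids, config$markers_per_cluster * k_shared)
    marker_pool <- split(pool, rep(seq_len(k_shared),
                                   each = config$markers_per_cluster))
    if (!is.null(enriched_markers)) {
      k <- enriched_markers$cluster
      abort_if(k > k_shared, "enriched cluster index out of range")
      pool_k <- setdiff(enriched_markers$genes, unlist(marker_pool[-k]))
      n_take <- min(length(pool_k),
                    round(enriched_markers$fraction *
                            config$markers_per_cluster))
      take <- sample(pool_k, n_take)
      marker_pool[[k]] <- c(take,
                            head(setdiff(marker_pool[[k]], take),
                                 config$markers_per_cluster - length(take)))
    }
    # drawn unconditionally to keep the stream aligned across species
    novel_program <- rlnorm(n_genes, 0, 1)
    novel_markers <- sample(setdiff(gene_ids, unlist(marker_pool)),
                            config$markers_per_cluster)
    list(base_w = base_w, marker_pool = marker_pool,
         novel_program = novel_program, novel_markers = novel_markers)
  })
  seed_off <- sum(utf8ToInt(species_label)) %% 1000L
  local_seed(config$seed + 505L + seed_off, {
    base_w <- world$base_w
    marker_pool <- world$marker_pool
    mito_w_total <- if (f_mito > 0) f_mito / (1 - f_mito) * sum(base_w) else 0
    mito_w <- rep(mito_w_total / n_mito, n_mito)
    profiles <- matrix(rep(base_w, k_total), n_genes, k_total)
    rownames(profiles) <- gene_ids
    for (k in seq_len(k_shared)) {
      profiles[marker_pool[[k]], k] <- profiles[marker_pool[[k]], k] * exp(2)
    }
    novel_id <- NULL
    if (has_novel) {
      novel_id <- k_total
      # a genuinely distinct expression program, not a marker tweak
      profiles[, k_total] <- world$novel_program
      profiles[world$novel_markers, k_total] <-
        profiles[world$novel_markers, k_total] * exp(2)
      marker_pool[[k_total]] <- world$novel_markers
    }
    # append mito weights and renormalise each cluster profile
    profiles <- rbind(profiles, matrix(rep(mito_w, k_total), n_mito, k_total))
    rownames(profiles) <- all_ids
    profiles <- sweep(profiles, 2, colSums(profiles), `/`)
    n_cells <- k_total * config$cells_per_cluster
    labels <- rep(seq_len(k_total), each = config$cells_per_cluster)
    cell_ids <- sprintf("%s_c%04d", species_label, seq_len(n_cells))
    depth <- rlnorm(n_cells, log(8000), 0.2)
    low_depth <- runif(n_cells) < 0.02
    depth[low_depth] <- runif(sum(low_depth), 150, 400)
    failing <- runif(n_cells) < 0.03 & !low_depth
    lam <- profiles[, labels, drop = FALSE]
    if (any(failing)) {
      # heavy mitochondrial load: re-weight the mito block of failing cells
      boost <- runif(sum(failing), 0.25, 0.60)
      mrow <- all_ids %in% mito_ids
      lam[, failing] <- sweep(lam[, failing, drop = FALSE], 2,
                              1 - colSums(lam[mrow, failing, drop = FALSE]),
                              `/`)
      lam[mrow, failing] <- rep(boost / n_mito, each = n_mito)
      lam[!mrow, failing] <- sweep(lam[!mrow, failing, drop = FALSE], 2,
                                   1 - boost, `*`)
    }
    counts <- matrix(rpois(length(lam), sweep(lam, 2, depth, `*`)),
                     nrow(lam), ncol(lam),
                     dimnames = list(all_ids, cell_ids))
    cm <- cell_matrix(counts, species = species_label)
    truth <- list(labels = setNames(labels, cell_ids),
                  marker_assignment = marker_pool,
                  species_specific_cluster_id = novel_id,
                  mito_gene_ids = mito_ids,
                  failing_cells = cell_ids[failing],
                  low_depth_cells = cell_ids[low_depth])
    list(matrix = cm, truth = truth)
  })
}

#' Write / read a cell matrix as MatrixMarket triplets
#'
#' Standard sparse exchange layout: `matrix.mtx` plus `genes.txt` and
#' `barcodes.txt` line lists.
#'
#' @param cm a [cell_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir` (write) or a [cell_matrix()] (read).
#' @export
write_cell_matrix_mtx <- function(cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(dir, "genes.txt"))
  writeLines(cm$cell_ids, file.path(dir, "barcodes.txt"))
  invisible(dir)
}

#' @param species species label to attach on read.
#' @rdname write_cell_matrix_mtx
#' @export
read_cell_matrix_mtx <- function(dir, species = NA_character_) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.txt"))
  colnames(m) <- readLines(file.path(dir, "barcodes.txt"))
  storage.mode(m) <- "integer"
  cell_matrix(m, species = species)
}
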