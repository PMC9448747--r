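#' Gene model set container
#'
#' A `gene_model_set` holds one transcript model per gene: the gene span,
#' strand, and sorted non-overlapping interval lists for exons, CDS and the
#' two UTRs. All coordinates are 1-based closed, matching GFF3.
#'
#' @param genes data.frame with columns `gene_id, chrom, strand, tx_start,
#'   tx_end`.
#' @param features data.frame with columns `gene_id, type, start, end`, where
#'   `type` is one of `exon, cds, utr5, utr3`.
#' @return An object of class `gene_model_set`.
#' @export
gene_model_set <- function(genes, features) {
  genes <- as.data.table(genes)
  features <- as.data.table(features)
  if (nrow(genes)) {
    abort_if(anyDuplicated(genes$gene_id) > 0, "duplicate gene ids")
    abort_if(!all(genes$strand %in% c("+", "-")), "strand must be + or -")
    abort_if(!all(features$type %in% c("exon", "cds", "utr5", "utr3")),
             "unknown feature type")
    abort_if(!all(features$gene_id %in% genes$gene_id),
             "feature references unknown gene")
  }
  setkey(features, gene_id, type, start)
  structure(list(genes = genes, features = features),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Simulate non-overlapping gene models
#'
#' Places `config$n_genes` strand-assigned gene models on the synthetic
#' genome. Each model is laid out left-to-right as
#' `UTR - intron - CDS exon(s) - intron - UTR`; on the minus strand the left
#' UTR is the 3' UTR. Genes are spaced at least `spacing_bp` apart so that the
#' 2 kb promoter window and the 150 bp flanks of neighbouring genes never
#' overlap, keeping region-category truth unambiguous.
#'
#' @param config a [sim_config()].
#' @param spacing_bp minimum gap between consecutive gene spans.
#' @return A [gene_model_set()]. Deterministic given `config$seed`.
#' @export
make_gene_models <- function(config, spacing_bp = 2500L) {
  validate_sim_config(config)
  n <- config$n_genes
  if (n == 0L) {
    return(gene_model_set(
      data.table(gene_id = character(), chrom = character(),
                 strand = character(), tx_start = integer(),
                 tx_end = integer()),
      data.table(gene_id = character(), type = character(),
                 start = integer(), end = integer())))
  }
  local_seed(config$seed + 101L, {
    per_chrom <- diff(round(seq(0, n, length.out = config$n_chroms + 1L)))
    gene_rows <- vector("list", n)
    feat_rows <- vector("list", n)
    gi <- 0L
    for (ci in seq_len(config$n_chroms)) {
      nc <- per_chrom[ci]
      if (nc == 0L) next
      chrom <- sprintf("chr%d", ci)
      # draw structures first so packing feasibility can be checked up front
      structs <- lapply(seq_len(nc), function(i) {
        n_cds <- sample(2:4, 1L)
        list(utr_a = sample(100:300, 1L),
             utr_b = sample(100:400, 1L),
             cds = sample(150:400, n_cds, replace = TRUE),
             introns = sample(300:1200, n_cds + 1L, replace = TRUE))
      })
      spans <- vapply(structs, function(s)
        s$utr_a + s$utr_b + sum(s$cds) + sum(s$introns), numeric(1))
      slack <- config$chrom_length_bp - sum(spans) - (nc + 1L) * spacing_bp
      abort_if(slack < 0,
               "infeasible packing: ", nc, " genes do not fit on ", chrom,
               " (", config$chrom_length_bp, " bp) with spacing ", spacing_bp)
      u <- runif(nc + 1L)
      extra <- floor(u / sum(u) * slack)
      pos <- spacing_bp + extra[1L]
      for (i in seq_len(nc)) {
        gi <- gi + 1L
        s <- structs[[i]]
        id <- sprintf("g%05d", gi)
        strand <- sample(c("+", "-"), 1L)
        tx_start <- as.integer(pos + 1L)
        # left-to-right block layout
        blocks <- list()
        cur <- tx_start
        add <- function(type, len) {
          blocks[[length(blocks) + 1L]] <<- list(type = type, start = cur,
                                                 end = cur + len - 1L)
          cur <<- cur + len
        }
        add("utr_a", s$utr_a)
        for (k in seq_along(s$cds)) {
          add("intron", s$introns[k])
          add("cds", s$cds[k])
        }
        add("intron", s$introns[length(s$introns)])
        add("utr_b", s$utr_b)
        tx_end <- as.integer(cur - 1L)
        bt <- rbindlist(lapply(blocks, as.data.table))
        bt[, type := as.character(type)]
        # strand decides which terminal UTR is 5'
        bt[type == "utr_a", type := if (strand == "+") "utr5" else "utr3"]
        bt[type == "utr_b", type := if (strand == "+") "utr3" else "utr5"]
        ex <- bt[type != "intron"]
        feats <- rbind(ex[, .(gene_id = id, type, start, end)],
                       ex[, .(gene_id = id, type = "exon", start, end)])
        gene_rows[[gi]] <- data.table(gene_id = id, chrom = chrom,
                                      strand = strand, tx_start = tx_start,
                                      tx_end = tx_end)
        feat_rows[[gi]] <- feats
        pos <- tx_end + spacing_bp + extra[i + 1L]
      }
    }
    feats <- rbindlist(feat_rows)
    feats[, type := ifelse(type == "cds", "cds", type)]
    gene_model_set(rbindlist(gene_rows), feats)
  })
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` features with `ID`/`Parent` attributes (one transcript
#' per gene), 1-based closed coordinates.
#'
#' @param models a [gene_model_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  type_map <- c(exon = "exon", cds = "CDS", utr5 = "five_prime_UTR",
                utr3 = "three_prime_UTR")
  g <- models$genes
  f <- merge(models$features, g[, .(gene_id, chrom, strand)], by = "gene_id")
  rows <- list(
    g[, .(seqid = chrom, type = "gene", start = tx_start, end = tx_end,
          strand, attr = sprintf("ID=%s", gene_id))],
    g[, .(seqid = chrom, type = "mRNA", start = tx_start, end = tx_end,
          strand, attr = sprintf("ID=%s.t1;Parent=%s", gene_id, gene_id))],
    f[, .(seqid = chrom, type = type_map[type], start, end, strand,
          attr = sprintf("Parent=%s.t1", gene_id))])
  tab <- rbindlist(rows)
  setorder(tab, seqid, start, type)
  lines <- c("##gff-version 3",
             tab[, sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                           seqid, "svscape_sim", type, start, end, strand,
                           attr)])
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file (via `rtracklayer`) into a [gene_model_set()]. Assumes
#' the one-transcript-per-gene layout written by [write_gff3()]: `CDS`,
#' `five_prime_UTR`, `three_prime_UTR` and `exon` children attached through
#' `Parent` chains to a `gene` feature.
#'
#' @param path GFF3 file path.
#' @return A [gene_model_set()].
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.table(as.data.frame(gr))
  df[, seqnames := as.character(seqnames)]
  df[, type := as.character(type)]
  df[, strand := as.character(strand)]
  genes <- df[type == "gene",
              .(gene_id = ID, chrom = seqnames, strand, tx_start = start,
                tx_end = end)]
  tx <- df[type == "mRNA", .(tx_id = ID, gene_id = vapply(Parent, `[`, "", 1L))]
  type_map <- c(exon = "exon", CDS = "cds", five_prime_UTR = "utr5",
                three_prime_UTR = "utr3")
  feats <- df[type %in% names(type_map),
              .(tx_id = vapply(Parent, `[`, "", 1L),
                type = type_map[type], start, end)]
  feats <- merge(feats, tx, by = "tx_id")[, .(gene_id, type, start, end)]
  gene_model_set(genes, feats)
}
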