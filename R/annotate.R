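# Region-category model
#
# Every SV gets exactly one of seven categories against the gene models:
#   exonic (CDS overlap) > UTR > intronic > promoter > upstream > downstream
#   > intergenic
# with the first match in that priority order winning across all overlapped
# genes. Strand-aware windows, 1-based closed:
#   promoter   = [TSS - promoter_bp, TSS - flank_bp - 1]
#   upstream   = [TSS - flank_bp, TSS - 1]
#   downstream = [3' gene end + 1, 3' gene end + flank_bp]
# mirrored for minus-strand genes. Insertions are evaluated at their
# insertion point, all other types as their [start, end] span.

CATEGORY_LEVELS <- c("exonic", "UTR", "intronic", "promoter", "upstream",
                     "downstream", "intergenic")

#' Per-gene region intervals
#'
#' Expands a gene model set into a table of categorised intervals: CDS
#' (`exonic`), UTRs (`UTR`), introns (gene span minus exons), promoter,
#' immediate upstream flank and downstream flank, with the promoter truncated
#' so the flank remains a distinct class. Coordinates below 1 are clipped.
#'
#' @param models a [gene_model_set()].
#' @param promoter_bp promoter window size upstream of the TSS (default 2000).
#' @param flank_bp immediate flank size (default 150).
#' @return data.table with columns `chrom, start, end, gene_id, category`.
#' @export
gene_regions <- function(models, promoter_bp = 2000L, flank_bp = 150L) {
  g <- models$genes
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      gene_id = character(), category = character())
  if (nrow(g) == 0L) return(empty)
  f <- merge(models$features, g[, .(gene_id, chrom)], by = "gene_id")
  cds <- f[type == "cds", .(chrom, start, end, gene_id, category = "exonic")]
  utr <- f[type %in% c("utr5", "utr3"),
           .(chrom, start, end, gene_id, category = "UTR")]
  # introns: gene span minus exons (exons are sorted and disjoint)
  introns <- f[type == "exon"][order(gene_id, start)][
    , {
      gaps_start <- head(end, -1L) + 1L
      gaps_end <- tail(start, -1L) - 1L
      keep <- gaps_end >= gaps_start
      .(chrom = chrom[1L], start = gaps_start[keep], end = gaps_end[keep])
    }, by = gene_id][, .(chrom, start, end, gene_id, category = "intronic")]
  plus <- g[strand == "+"]
  minus <- g[strand == "-"]
  flanks <- rbind(
    plus[, .(chrom, start = tx_start - promoter_bp,
             end = tx_start - flank_bp - 1L, gene_id, category = "promoter")],
    plus[, .(chrom, start = tx_start - flank_bp, end = tx_start - 1L,
             gene_id, category = "upstream")],
    plus[, .(chrom, start = tx_end + 1L, end = tx_end + flank_bp,
             gene_id, category = "downstream")],
    minus[, .(chrom, start = tx_end + flank_bp + 1L,
              end = tx_end + promoter_bp, gene_id, category = "promoter")],
    minus[, .(chrom, start = tx_end + 1L, end = tx_end + flank_bp,
              gene_id, category = "upstream")],
    minus[, .(chrom, start = tx_start - flank_bp, end = tx_start - 1L,
              gene_id, category = "downstream")])
  out <- rbind(cds, utr, introns, flanks)
  out[, start := pmax(start, 1L)]
  out <- out[end >= start]
  setorder(out, chrom, start)
  out[]
}

sv_query_spans <- function(svs) {
  # INS is a point event at its insertion coordinate
  data.table(chrom = svs$chrom,
             start = svs$start,
             end = ifelse(svs$svtype == "INS", svs$start, svs$end))
}

#' Classify SVs into genomic region categories
#'
#' Assigns each SV exactly one category by overlap against the per-gene region
#' intervals of [gene_regions()], resolving multi-region overlaps by the fixed
#' priority `exonic > UTR > intronic > promoter > upstream > downstream`;
#' SVs overlapping no gene footprint are `intergenic`. Deletions additionally
#' receive a coding-effect call (see [coding_effect()]).
#'
#' @param svs data.frame with columns `id, chrom, start, end, svtype`.
#' @param models a [gene_model_set()].
#' @param promoter_bp,flank_bp window sizes, see [gene_regions()].
#' @param unknown_chrom `"warn"` (classify as intergenic with a warning) or
#'   `"error"` for SVs on chromosomes absent from the models.
#' @return data.table `sv_id, category, gene_ids, coding_effect` with
#'   `category` a factor over the seven levels and `gene_ids` a comma-joined
#'   string of overlapped genes (extended footprint), empty for intergenic.
#' @export
classify_svs <- function(svs, models, promoter_bp = 2000L, flank_bp = 150L,
                         unknown_chrom = c("warn", "error")) {
  unknown_chrom <- match.arg(unknown_chrom)
  svs <- as.data.table(svs)
  abort_if(!all(c("id", "chrom", "start", "end", "svtype") %in% names(svs)),
           "svs must have columns id, chrom, start, end, svtype")
  regions <- gene_regions(models, promoter_bp, flank_bp)
  if (nrow(models$genes) && unknown_chrom == "error") {
    bad <- setdiff(unique(svs$chrom), unique(models$genes$chrom))
    abort_if(length(bad) > 0, "SVs on unknown chromosome(s): ",
             paste(bad, collapse = ", "))
  } else if (nrow(models$genes)) {
    bad <- setdiff(unique(svs$chrom), unique(models$genes$chrom))
    if (length(bad))
      warning("SVs on chromosome(s) absent from models classified intergenic: ",
              paste(bad, collapse = ", "), call. = FALSE)
  }
  q <- sv_query_spans(svs)
  out <- data.table(sv_id = as.character(svs$id),
                    category = factor("intergenic", levels = CATEGORY_LEVELS),
                    gene_ids = "",
                    coding_effect = "none")
  if (nrow(regions)) {
    qgr <- GenomicRanges::GRanges(q$chrom, IRanges::IRanges(q$start, q$end))
    rgr <- GenomicRanges::GRanges(regions$chrom,
                                  IRanges::IRanges(regions$start, regions$end))
    hits <- GenomicRanges::findOverlaps(qgr, rgr, ignore.strand = TRUE)
    if (length(hits)) {
      ht <- data.table(qi = S4Vectors::queryHits(hits),
                       ri = S4Vectors::subjectHits(hits))
      ht[, category := regions$category[ri]]
      ht[, gene_id := regions$gene_id[ri]]
      ht[, rank := match(category, CATEGORY_LEVELS)]
      best <- ht[, .(category = CATEGORY_LEVELS[min(rank)],
                     gene_ids = paste(sort(unique(gene_id)), collapse = ",")),
                 by = qi]
      out[best$qi, `:=`(category = factor(best$category,
                                          levels = CATEGORY_LEVELS),
                        gene_ids = best$gene_ids)]
    }
  }
  # frameshift/inframe arithmetic for deletions
  del <- which(svs$svtype == "DEL" & out$gene_ids != "")
  if (length(del)) {
    cds <- regions[category == "exonic"]
    if (nrow(cds)) {
      dgr <- GenomicRanges::GRanges(q$chrom[del],
                                    IRanges::IRanges(q$start[del], q$end[del]))
      cgr <- GenomicRanges::GRanges(cds$chrom,
                                    IRanges::IRanges(cds$start, cds$end))
      hits <- GenomicRanges::findOverlaps(dgr, cgr, ignore.strand = TRUE)
      if (length(hits)) {
        ht <- data.table(qi = S4Vectors::queryHits(hits),
                         ri = S4Vectors::subjectHits(hits))
        ht[, ov := pmin(q$end[del][qi], cds$end[ri]) -
                   pmax(q$start[del][qi], cds$start[ri]) + 1L]
        ht[, gene_id := cds$gene_id[ri]]
        per_gene <- ht[, .(ov = sum(ov)), by = .(qi, gene_id)]
        eff <- per_gene[, .(effect = if (any(ov %% 3L != 0L)) "frameshift"
                                     else "inframe"), by = qi]
        out[del[eff$qi], coding_effect := eff$effect]
      }
    }
  }
  out[]
}

#' Classify a single SV
#'
#' Convenience wrapper around [classify_svs()] for one record.
#'
#' @param sv a one-row data.frame or list with `id, chrom, start, end, svtype`.
#' @inheritParams classify_svs
#' @return A one-row annotation data.table.
#' @export
classify_sv <- function(sv, models, promoter_bp = 2000L, flank_bp = 150L) {
  classify_svs(as.data.table(as.list(sv)), models, promoter_bp, flank_bp)
}

#' Coding effect of a deletion on one gene model
#'
#' Counts the CDS bases removed by a deletion span and calls `frameshift` if
#' that count is positive and not divisible by 3, `inframe` if positive and
#' divisible by 3, and `none` otherwise. Non-deletion SV types return `none`.
#'
#' @param sv list/one-row data.frame with `chrom, start, end, svtype`.
#' @param model a [gene_model_set()] restricted to (or containing) the gene of
#'   interest; all CDS intervals on the SV's chromosome are considered.
#' @return `"frameshift"`, `"inframe"` or `"none"`.
#' @export
coding_effect <- function(sv, model) {
  if (sv$svtype != "DEL") return("none")
  cds <- merge(model$features[type == "cds"],
               model$genes[, .(gene_id, chrom)], by = "gene_id")
  cds <- cds[chrom == sv$chrom]
  if (nrow(cds) == 0L) return("none")
  ov <- pmin(sv$end, cds$end) - pmax(sv$start, cds$start) + 1L
  total <- sum(ov[ov > 0])
  if (total == 0L) "none" else if (total %% 3L != 0L) "frameshift" else "inframe"
}

#' Gene lists from high-FST SV annotations
#'
#' Builds the two candidate gene lists used downstream: genes carrying at
#' least one high-FST SV in any non-intergenic category (`list1`), and genes
#' carrying at least one high-FST SV classified `exonic` or `promoter`
#' (`list2`, a subset of `list1`).
#'
#' @param annotations output of [classify_svs()].
#' @param high_fst_ids character vector of selected (high-FST) SV ids; must
#'   all be present in `annotations$sv_id`.
#' @return `list(list1 = , list2 = )` of sorted gene-id character vectors.
#' @export
gene_category_lists <- function(annotations, high_fst_ids) {
  annotations <- as.data.table(annotations)
  abort_if(!all(high_fst_ids %in% annotations$sv_id),
           "annotations must cover every high-FST SV id")
  sel <- annotations[sv_id %in% high_fst_ids & gene_ids != ""]
  split_genes <- function(x) {
    g <- unique(unlist(strsplit(x, ",", fixed = TRUE)))
    if (is.null(g)) character() else sort(g)
  }
  list(list1 = split_genes(sel[category != "intergenic"]$gene_ids),
       list2 = split_genes(sel[category %in% c("exonic", "promoter")]$gene_ids))
}

#' Write an SV annotation table
#'
#' @param annotations output of [classify_svs()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  fwrite(as.data.table(annotations), path, sep = "\t")
  invisible(path)
}
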