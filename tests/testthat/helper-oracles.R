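# Independent oracles used to check pipeline results. These reimplement the
# target quantities from first principles and must stay independent of the
# package code paths they verify.

# Weir & Cockerham (1984) per-site theta-hat for two populations, written
# directly from the textbook variance components using genotype vectors
# (0/1/2 alt-allele counts, NA = missing). Returns NA when undefined.
oracle_wc_fst <- function(ga, gb) {
  ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
  if (length(ga) == 0 || length(gb) == 0) return(NA_real_)
  r <- 2
  n <- c(length(ga), length(gb))
  p <- c(sum(ga) / (2 * n[1]), sum(gb) / (2 * n[2]))
  h <- c(mean(ga == 1), mean(gb == 1))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  den <- a + b + cc
  if (abs(den) < .Machine$double.eps) NA_real_ else a / den
}

# Brute-force region classifier: walk every gene, rebuild its regions from
# the feature table from first principles, collect overlapped categories and
# apply the priority order. sv: list(chrom, start, end, svtype).
oracle_classify <- function(sv, models, promoter_bp = 2000, flank_bp = 150) {
  priority <- c("exonic", "UTR", "intronic", "promoter", "upstream",
                "downstream", "intergenic")
  qs <- sv$start
  qe <- if (sv$svtype == "INS") sv$start else sv$end
  hit <- function(s, e) any(qs <= e & qe >= s)
  cats <- character()
  genes <- character()
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i]
    if (g$chrom != sv$chrom) next
    f <- models$features[gene_id == g$gene_id]
    cds <- f[type == "cds"]
    utr <- f[type %in% c("utr5", "utr3")]
    ex <- f[type == "exon"][order(start)]
    found <- character()
    if (nrow(cds) && hit(cds$start, cds$end)) found <- c(found, "exonic")
    if (nrow(utr) && hit(utr$start, utr$end)) found <- c(found, "UTR")
    if (nrow(ex) > 1) {
      is_ <- head(ex$end, -1) + 1
      ie <- tail(ex$start, -1) - 1
      ok <- ie >= is_
      if (any(ok) && hit(is_[ok], ie[ok])) found <- c(found, "intronic")
    }
    if (g$strand == "+") {
      prom <- c(g$tx_start - promoter_bp, g$tx_start - flank_bp - 1)
      up <- c(g$tx_start - flank_bp, g$tx_start - 1)
      down <- c(g$tx_end + 1, g$tx_end + flank_bp)
    } else {
      prom <- c(g$tx_end + flank_bp + 1, g$tx_end + promoter_bp)
      up <- c(g$tx_end + 1, g$tx_end + flank_bp)
      down <- c(g$tx_start - flank_bp, g$tx_start - 1)
    }
    prom[1] <- max(prom[1], 1); up[1] <- max(up[1], 1); down[1] <- max(down[1], 1)
    if (prom[2] >= prom[1] && hit(prom[1], prom[2])) found <- c(found, "promoter")
    if (up[2] >= up[1] && hit(up[1], up[2])) found <- c(found, "upstream")
    if (down[2] >= down[1] && hit(down[1], down[2])) found <- c(found, "downstream")
    if (length(found)) {
      cats <- c(cats, found)
      genes <- c(genes, g$gene_id)
    }
  }
  if (length(cats) == 0) return(list(category = "intergenic",
                                     gene_ids = character()))
  list(category = priority[min(match(cats, priority))],
       gene_ids = sort(unique(genes)))
}

# Exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric point
# probabilities not exceeding that of the observed table (with the standard
# relative tolerance), margins fixed.
oracle_fisher_two_sided <- function(tab) {
  m <- sum(tab[1, ])   # white balls (row 1)
  n <- sum(tab[2, ])   # black balls
  k <- sum(tab[, 1])   # drawn
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand median-of-ratios size factors (direct formula, geometric mean rescale).
oracle_size_factors <- function(counts) {
  geo <- exp(rowMeans(log(counts)))
  ok <- geo > 0 & is.finite(geo)
  sf <- apply(counts, 2, function(col) median(col[ok] / geo[ok]))
  sf / exp(mean(log(sf)))
}

# A small hand-built gene model set spanning both strands, used by the
# annotation tests. Layout (chr1):
#   gA (+): tx 10000..13999, exons [10000-10299 utr5][11000-11599 cds]
#           [12600-12899 cds][13700-13999 utr3]
#   gB (-): tx 30000..33999, mirrored roles
toy_models <- function() {
  genes <- data.table::data.table(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    tx_start = c(10000L, 30000L), tx_end = c(13999L, 33999L))
  feat <- function(g, type, s, e) data.table::data.table(
    gene_id = g, type = type, start = s, end = e)
  fa <- rbind(feat("gA", "utr5", 10000L, 10299L),
              feat("gA", "cds", 11000L, 11599L),
              feat("gA", "cds", 12600L, 12899L),
              feat("gA", "utr3", 13700L, 13999L))
  fb <- rbind(feat("gB", "utr3", 30000L, 30299L),
              feat("gB", "cds", 31000L, 31599L),
              feat("gB", "cds", 32600L, 32899L),
              feat("gB", "utr5", 33700L, 33999L))
  f <- rbind(fa, fb)
  gene_model_set(genes, rbind(f, data.table::copy(f)[, type := "exon"]))
}

# Genotype matrix built directly from a codes matrix.
toy_gm <- function(codes, qual = 60) {
  n <- nrow(codes)
  genotype_matrix(codes, data.table::data.table(
    id = sprintf("sv%03d", seq_len(n)), chrom = "chr1",
    start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 99L,
    svtype = "DEL", length_bp = 100L, qual = qual))
}

toy_popmap <- function(n_a, n_b, labels = c("cattle", "yak")) {
  data.table::data.table(
    sample = c(sprintf("a%02d", seq_len(n_a)), sprintf("b%02d", seq_len(n_b))),
    population = rep(labels, c(n_a, n_b)))
}
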