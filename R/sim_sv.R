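# Synthetic SV cohort.
#
# Placement draws a region category first (configurable probabilities), then a
# concrete locus whose span lies wholly inside an interval of that category,
# so the intended category is also the classified one. SV start positions on
# a chromosome are kept >= 150 bp apart: combined with per-sample breakpoint
# jitter bounded at +-20 bp (start) and +-5 bp (length), calls from the same
# SV always chain at merge distance 50 while calls from different SVs never
# do.

SVTYPE_PROBS <- c(DEL = 0.470, INS = 0.503, DUP = 0.0219, INV = 0.0055)

intergenic_pool <- function(models, config, promoter_bp = 2000L,
                            flank_bp = 150L, margin = 50L) {
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  g <- models$genes
  pools <- lapply(chroms, function(ch) {
    len <- as.integer(config$chrom_length_bp)
    sub <- g[chrom == ch]
    if (nrow(sub) == 0) {
      return(data.table(chrom = ch, start = 1L, end = len))
    }
    # complement of the extended footprints, with a safety margin
    fp_start <- pmax(1L, sub$tx_start - promoter_bp - margin)
    fp_end <- pmin(len, sub$tx_end + promoter_bp + margin)
    o <- order(fp_start)
    fp_start <- fp_start[o]; fp_end <- fp_end[o]
    gaps_start <- c(1L, fp_end + 1L)
    gaps_end <- c(fp_start - 1L, len)
    keep <- gaps_end >= gaps_start
    data.table(chrom = ch, start = gaps_start[keep], end = gaps_end[keep])
  })
  rbindlist(pools)
}

place_in_pool <- function(pool, lens) {
  # sample an interval (width-weighted), then clip the span to fit it, so
  # long spans do not pile up in the few widest intervals of a pool
  n <- length(lens)
  width <- pool$end - pool$start + 1L
  ok <- which(width >= 52L)
  abort_if(length(ok) == 0, "no region interval can hold an SV span")
  start <- integer(n)
  chrom <- character(n)
  len_used <- integer(n)
  for (i in seq_len(n)) {
    j <- ok[sample.int(length(ok), 1L, prob = width[ok])]
    len_used[i] <- min(lens[i], width[j] - 2L)
    max_off <- width[j] - len_used[i]
    start[i] <- pool$start[j] + sample.int(max_off, 1L) - 1L
    chrom[i] <- pool$chrom[j]
  }
  data.table(chrom = chrom, start = start, len = len_used)
}

#' Simulate an SV cohort for two populations
#'
#' Generates `config$n_sv` SV sites placed into defined genomic contexts,
#' draws per-sample diploid genotypes under Hardy-Weinberg equilibrium, and
#' materialises one single-sample call set per individual with jittered
#' breakpoints (the caller's view). Background SVs share one allele frequency
#' across both populations, drawn from a symmetric Beta(0.8, 0.8);
#' `config$n_divergent_sv` sites instead get `p_A = (1 + delta)/2` and
#' `p_B = (1 - delta)/2`, so `delta = 1` is a fixed difference (alternate
#' fixed in population A, absent in B). Divergent sites are modelled as
#' confidently genotyped (full call rate, high site quality); a configurable
#' slice of background sites carries missing genotypes or sub-threshold
#' quality to exercise the downstream filters.
#'
#' @param models a [gene_model_set()]; required non-empty whenever
#'   `category_probs` puts mass on genic categories.
#' @param config a [sim_config()].
#' @return An object of class `sv_cohort`: list with `svs` (truth site table
#'   incl. placement category, gene id, per-population frequencies and the
#'   divergent flag), `callsets` (named list of single-sample
#'   [sv_callset()]s containing carrier and missing-genotype records),
#'   `genotypes` (true [genotype_matrix()] over all samples), `popmap`, and
#'   `truth` (divergent ids, placement map, population labels).
#' @export
simulate_sv_cohort <- function(models, config) {
  validate_sim_config(config)
  abort_if(config$divergence_delta > 1, "divergence_delta must be <= 1")
  genic <- setdiff(names(config$category_probs), "intergenic")
  if (sum(config$category_probs[genic]) > 0)
    abort_if(nrow(models$genes) == 0,
             "genic placement requested but gene model set is empty")
  local_seed(config$seed + 202L, {
    n <- config$n_sv
    regions <- gene_regions(models)
    pools <- c(split(regions, by = "category"),
               list(intergenic = intergenic_pool(models, config)))
    category <- sample(names(config$category_probs), n, replace = TRUE,
                       prob = config$category_probs)
    svtype <- sample(names(SVTYPE_PROBS), n, replace = TRUE,
                     prob = SVTYPE_PROBS)
    len <- pmin(2000L, 50L + as.integer(round(rexp(n, 1 / 150))))
    svs <- data.table(id = sprintf("sv%05d", seq_len(n)),
                      svtype = svtype, length_bp = len, category = category)
    # spans must fit the category interval; insertions are points
    svs[, span := ifelse(svtype == "INS", 1L, length_bp)]
    placed <- vector("list", length(pools))
    for (cat_name in unique(svs$category)) {
      idx <- which(svs$category == cat_name)
      pool <- pools[[cat_name]]
      abort_if(is.null(pool) || nrow(pool) == 0,
               "no placement pool for category ", cat_name)
      loc <- place_in_pool(pool, svs$span[idx])
      svs[idx, `:=`(chrom = loc$chrom, start = loc$start)]
      svs[idx, length_bp := ifelse(svtype == "INS", length_bp, loc$len)]
      svs[idx, span := ifelse(svtype == "INS", 1L, length_bp)]
    }
    # enforce >= 150 bp between SV starts per chromosome by resampling clashes
    for (round in 1:100) {
      setorder(svs, chrom, start)
      clash <- svs[, {
        d <- c(Inf, diff(start))
        .(id = id[d < 150])
      }, by = chrom]$id
      if (length(clash) == 0) break
      abort_if(round == 100, "could not place SVs with 150 bp separation; ",
               "genome too dense for n_sv")
      for (sid in clash) {
        i <- which(svs$id == sid)
        loc <- place_in_pool(pools[[svs$category[i]]], svs$span[i])
        svs[i, `:=`(chrom = loc$chrom, start = loc$start)]
        svs[i, length_bp := ifelse(svtype == "INS", length_bp, loc$len)]
        svs[i, span := ifelse(svtype == "INS", 1L, length_bp)]
      }
    }
    setorder(svs, id)
    svs[, end := ifelse(svtype == "INS", start, start + length_bp - 1L)]
    svs[, span := NULL]
    # gene context of the placement (for genic categories)
    if (nrow(regions)) {
      ann <- classify_svs(svs[, .(id, chrom, start, end, svtype)], models)
      svs[, gene_id := vapply(strsplit(ann$gene_ids, ","), function(x)
        if (length(x)) x[1] else NA_character_, character(1))]
    } else {
      svs[, gene_id := NA_character_]
    }
    # allele frequencies
    divergent_ids <- if (config$n_divergent_sv > 0)
      sort(sample(svs$id, config$n_divergent_sv)) else character()
    svs[, divergent := id %in% divergent_ids]
    p_shared <- rbeta(n, 0.8, 0.8)
    delta <- config$divergence_delta
    svs[, p_a := ifelse(divergent, (1 + delta) / 2, p_shared)]
    svs[, p_b := ifelse(divergent, (1 - delta) / 2, p_shared)]
    # site quality: a low-quality slice among background sites
    svs[, qual := pmax(35, rnorm(n, 60, 10))]
    low_q <- !svs$divergent & runif(n) < config$low_qual_rate
    svs[low_q, qual := pmax(5, rnorm(sum(low_q), 20, 3))]
    svs[, qual := round(qual, 1)]
    # genotypes under HWE
    n_a <- config$n_samples_pop_a
    n_b <- config$n_samples_pop_b
    samples <- c(sprintf("%s%02d", config$pop_a_label, seq_len(n_a)),
                 sprintf("%s%02d", config$pop_b_label, seq_len(n_b)))
    codes <- cbind(
      matrix(rbinom(n * n_a, 2, rep(svs$p_a, n_a)), n, n_a),
      matrix(rbinom(n * n_b, 2, rep(svs$p_b, n_b)), n, n_b))
    colnames(codes) <- samples
    miss <- matrix(runif(n * (n_a + n_b)) < config$missing_rate, n, n_a + n_b)
    miss[svs$divergent, ] <- FALSE
    codes[miss] <- NA_integer_
    popmap <- data.table(
      sample = samples,
      population = rep(c(config$pop_a_label, config$pop_b_label),
                       c(n_a, n_b)))
    gm <- genotype_matrix(codes, svs[, .(id, chrom, start, end, svtype,
                                         length_bp, qual)])
    # per-sample call sets: carriers plus missing-genotype records,
    # breakpoints jittered within the merge radius
    callsets <- lapply(samples, function(s) {
      v <- codes[, s]
      rows <- which(is.na(v) | v > 0L)
      rec <- svs[rows, .(id, chrom, start, end, svtype, length_bp, qual)]
      m <- nrow(rec)
      js <- pmax(-20L, pmin(20L, as.integer(round(rnorm(m, 0, 8)))))
      jl <- sample(-5:5, m, replace = TRUE)
      rec[, start := start + js]
      rec[, length_bp := pmax(40L, length_bp + jl)]
      rec[, end := ifelse(svtype == "INS", start, start + length_bp - 1L)]
      rec[, qual := round(pmax(5, qual + rnorm(m, 0, 2)), 1)]
      gt <- matrix(v[rows], m, 1, dimnames = list(rec$id, s))
      sv_callset(rec, gt)
    })
    names(callsets) <- samples
    truth <- list(divergent_sv_ids = divergent_ids,
                  sv_placement = svs[, .(sv_id = id, category, gene_id)],
                  pop_a_label = config$pop_a_label,
                  pop_b_label = config$pop_b_label)
    structure(list(svs = svs, callsets = callsets, genotypes = gm,
                   popmap = popmap, truth = truth),
              class = "sv_cohort")
  })
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat("sv_cohort:", nrow(x$svs), "SVs (",
      sum(x$svs$divergent), "divergent ) x", nrow(x$popmap), "samples\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits one VCF per sample, the population map TSV, and a truth JSON
#' (divergent ids, placements, per-SV frequencies).
#'
#' @param cohort a `sv_cohort` from [simulate_sv_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$callsets)) {
    write_sv_vcf(cohort$callsets[[s]], file.path(dir, paste0(s, ".vcf")))
  }
  write_population_map(cohort$popmap, file.path(dir, "popmap.tsv"))
  truth <- cohort$truth
  truth$svs <- cohort$svs
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       dataframe = "columns")
  invisible(dir)
}

#' One-to-one ortholog map between two gene sets
#'
#' Pairs `fraction_shared` of the smaller gene set one-to-one with genes of
#' the other set; remaining genes are unmapped (species-specific). Sampled
#' genes on each side are paired in sorted order, so identical gene sets with
#' `fraction_shared = 1` give the identity map.
#'
#' @param models_a,models_b [gene_model_set()] objects (or character vectors
#'   of gene ids).
#' @param fraction_shared fraction of the smaller set to pair, in `[0, 1]`.
#' @param seed integer seed.
#' @return data.table `gene_a, gene_b`, one row per ortholog pair.
#' @export
make_ortholog_map <- function(models_a, models_b, fraction_shared = 0.9,
                              seed = 1L) {
  abort_if(fraction_shared < 0 || fraction_shared > 1,
           "fraction_shared must lie in [0, 1]")
  ids_a <- if (is.character(models_a)) models_a else models_a$genes$gene_id
  ids_b <- if (is.character(models_b)) models_b else models_b$genes$gene_id
  n_pairs <- round(fraction_shared * min(length(ids_a), length(ids_b)))
  if (n_pairs == 0)
    return(data.table(gene_a = character(), gene_b = character()))
  local_seed(seed + 303L, {
    # genes present under the same id in both sets are true orthologs and are
    # paired with themselves; only the remainder is paired arbitrarily
    shared <- intersect(ids_a, ids_b)
    n_id <- min(n_pairs, length(shared))
    a <- sample(shared, n_id)
    b <- a
    extra <- n_pairs - n_id
    if (extra > 0) {
      a <- c(a, sample(setdiff(ids_a, a), extra))
      b <- c(b, sample(setdiff(ids_b, b), extra))
    }
    o <- order(a)
    data.table(gene_a = a[o], gene_b = b[o])
  })
}
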