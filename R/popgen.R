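# Per-site two-population FST.
#
# Default estimator: Weir & Cockerham (1984) theta-hat = a / (a + b + c),
# computed from genotype counts (allele frequencies AND observed
# heterozygosity), the convention used by standard VCF tooling. Estimates can
# be slightly negative and are reported unclamped. A site is undefined when
# either population has zero called genotypes or the variance denominator is
# zero (monomorphic across both populations).

popmap_to_factor <- function(popmap, samples) {
  popmap <- as.data.table(popmap)
  idx <- match(samples, popmap$sample)
  abort_if(anyNA(idx), "sample(s) missing from population map: ",
           paste(head(samples[is.na(idx)], 5), collapse = ", "))
  setNames(popmap$population[idx], samples)
}

#' Per-population alternate-allele frequencies
#'
#' `p-hat = alternate allele count / (2 x called diploids)`, missing genotypes
#' excluded. Sites with zero called genotypes get `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap data.frame `sample, population`.
#' @param population population label to tabulate.
#' @return data.table `sv_id, p_hat, n_called`.
#' @export
allele_frequency <- function(gm, popmap, population) {
  pops <- popmap_to_factor(popmap, colnames(gm$codes))
  abort_if(!population %in% pops, "population not present in map: ", population)
  sub <- gm$codes[, pops == population, drop = FALSE]
  n_called <- rowSums(!is.na(sub))
  ac <- rowSums(sub, na.rm = TRUE)
  data.table(sv_id = gm$sites$id,
             p_hat = ifelse(n_called > 0, ac / (2 * n_called), NA_real_),
             n_called = n_called)
}

wc_theta <- function(p, h, n) {
  # p, h, n: length-2 vectors of alt frequency, observed het frequency and
  # called diploid count per population. Returns c(a, b, c) components.
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  inner_a <- pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4
  inner_b <- pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar
  if (nbar > 1) {
    a <- (nbar / nc) * (s2 - inner_a / (nbar - 1))
    b <- (nbar / (nbar - 1)) * inner_b
  } else {
    # single diploid per population: the finite-sample corrections are 0/0;
    # they vanish when their numerators do (e.g. a fixed difference), and the
    # estimate is undefined otherwise
    a <- if (inner_a == 0) (nbar / nc) * s2 else NaN
    b <- if (inner_b == 0) 0 else NaN
  }
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Per-SV FST between two populations
#'
#' @param gm a [genotype_matrix()] with diploid codes.
#' @param popmap data.frame `sample, population` using exactly two labels
#'   across the matrix samples.
#' @param estimator `"weir_cockerham"` (default) or `"hudson"` (Bhatia et al.
#'   ratio-of-averages numerator/denominator evaluated per site).
#' @return data.table `sv_id, fst, p_hat_a, p_hat_b, n_called_a, n_called_b`
#'   where populations a/b follow the sort order of the two labels; `fst` is
#'   `NA` for undefined sites (monomorphic, or a population with zero called
#'   genotypes).
#' @export
fst_per_sv <- function(gm, popmap, estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  pops <- popmap_to_factor(popmap, colnames(gm$codes))
  labels <- sort(unique(pops))
  abort_if(length(labels) != 2,
           "exactly two population labels required, got: ",
           paste(labels, collapse = ", "))
  a_cols <- pops == labels[1]
  b_cols <- pops == labels[2]
  stats_for <- function(cols) {
    sub <- gm$codes[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    p <- ifelse(n > 0, rowSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, rowSums(sub == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  A <- stats_for(a_cols)
  B <- stats_for(b_cols)
  n_sites <- nrow(gm$codes)
  fst <- rep(NA_real_, n_sites)
  defined <- A$n > 0 & B$n > 0
  if (estimator == "weir_cockerham") {
    for (i in which(defined)) {
      comp <- wc_theta(c(A$p[i], B$p[i]), c(A$h[i], B$h[i]),
                       c(A$n[i], B$n[i]))
      denom <- sum(comp)
      fst[i] <- if (is.na(denom) || abs(denom) < .Machine$double.eps)
        NA_real_ else comp[["a"]] / denom
    }
  } else {
    p1 <- A$p; p2 <- B$p
    m1 <- 2 * A$n; m2 <- 2 * B$n  # allele sample sizes
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    ok <- defined & den > 0 & m1 > 1 & m2 > 1
    fst[ok] <- (num / den)[ok]
  }
  data.table(sv_id = gm$sites$id, fst = fst,
             p_hat_a = A$p, p_hat_b = B$p,
             n_called_a = A$n, n_called_b = B$n)
}

#' Select the top fraction of FST values
#'
#' Undefined (`NA`) estimates are excluded from numerator and denominator;
#' `k = ceiling(fraction * n_defined)` largest values are selected, and every
#' site tied with the k-th value is included, so the selection may exceed `k`.
#'
#' @param fst_results output of [fst_per_sv()] (or any data.frame with
#'   `sv_id, fst`).
#' @param fraction top fraction to select, in `(0, 1]` (default 0.005, i.e.
#'   the top 0.5%).
#' @return Character vector of selected SV ids (possibly empty, with a
#'   warning, when no site has a defined estimate).
#' @export
select_top_fraction <- function(fst_results, fraction = 0.005) {
  abort_if(!is.numeric(fraction) || fraction <= 0 || fraction > 1,
           "fraction must lie in (0, 1]")
  dt <- as.data.table(fst_results)
  def <- dt[!is.na(fst)]
  if (nrow(def) == 0) {
    warning("no defined FST values; returning empty selection", call. = FALSE)
    return(character())
  }
  k <- ceiling(fraction * nrow(def))
  thr <- sort(def$fst, decreasing = TRUE)[k]
  def[fst >= thr, sv_id]
}

#' Write the FST result table
#'
#' Joins per-SV site information onto the FST results and flags the selected
#' high-FST set.
#'
#' @param fst_results output of [fst_per_sv()].
#' @param gm the [genotype_matrix()] the results were computed from.
#' @param selected character vector of selected SV ids.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fst_table <- function(fst_results, gm, selected, path) {
  tab <- merge(gm$sites[, .(sv_id = id, chrom, start, end, svtype)],
               as.data.table(fst_results), by = "sv_id", sort = FALSE)
  tab[, selected_flag := sv_id %in% selected]
  fwrite(tab, path, sep = "\t")
  invisible(path)
}
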