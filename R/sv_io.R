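SV_TYPES <- c("DEL", "INS", "DUP", "INV")

#' SV call set container
#'
#' A `sv_callset` couples a table of SV site records with a genotype matrix
#' coded as alternate-allele counts (0/1/2, `NA` = missing). Single-sample
#' call sets (one VCF per individual, the caller's native output) and merged
#' multi-sample sets share this representation.
#'
#' @param records data.frame with columns `id, chrom, start, end, svtype,
#'   length_bp, qual` (optionally `support`).
#' @param gt integer matrix, rows = records (rownames = ids), columns =
#'   samples; values in `{0, 1, 2, NA}`.
#' @return An object of class `sv_callset`.
#' @export
sv_callset <- function(records, gt) {
  records <- as.data.table(records)
  gt <- as.matrix(gt)
  abort_if(nrow(records) != nrow(gt), "records/genotype row mismatch")
  abort_if(!all(records$svtype %in% SV_TYPES), "svtype outside DEL/INS/DUP/INV")
  if (nrow(records)) {
    abort_if(any(records$end < records$start), "end must be >= start")
    abort_if(any(records$svtype == "INS" & records$end != records$start),
             "INS records must have end == start")
    abort_if(any(records$length_bp <= 0), "length_bp must be positive")
    ok <- gt %in% c(0L, 1L, 2L) | is.na(gt)
    abort_if(!all(ok), "genotype codes must be 0/1/2/NA")
  }
  rownames(gt) <- records$id
  structure(list(records = records, gt = gt), class = "sv_callset")
}

#' @export
print.sv_callset <- function(x, ...) {
  cat("sv_callset:", nrow(x$records), "records,", ncol(x$gt), "sample(s)")
  sk <- attr(x, "skipped")
  if (!is.null(sk) && sk > 0) cat(" (", sk, " non-SV records skipped)", sep = "")
  cat("\n")
  invisible(x)
}

gt_to_code <- function(gt_str) {
  alleles <- strsplit(sub(":.*$", "", gt_str), "[/|]")
  vapply(alleles, function(a) {
    if (any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
}

code_to_gt <- function(code) {
  out <- c("0/0", "0/1", "1/1")[code + 1L]
  out[is.na(code)] <- "./."
  out
}

#' Read an SV VCF
#'
#' Parses a VCF 4.x file in the long-read SV caller dialect: `SVTYPE`,
#' `SVLEN` and `END` in INFO, `GT` as the first FORMAT field. Records whose
#' `SVTYPE` is outside `DEL/INS/DUP/INV` (breakends, translocations) are
#' skipped and counted in the `skipped` attribute; a retained record missing
#' `SVTYPE` is a parse error. Negative `SVLEN` (deletion convention) is
#' stored as a positive `length_bp`; when `SVLEN` is absent the length is
#' `END - POS`. Internally a record spans `[start, start + length_bp - 1]`
#' (insertions are points: `end == start`).
#'
#' @param path VCF file path (plain text).
#' @return A [sv_callset()] with attribute `skipped`.
#' @export
read_sv_vcf <- function(path) {
  abort_if(!file.exists(path), "cannot read VCF: ", path)
  lines <- readLines(path)
  abort_if(length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF"),
           "not a VCF 4.x file: ", path)
  hdr <- grep("^#CHROM", lines)
  abort_if(length(hdr) != 1, "missing #CHROM header line in ", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9) cols[10:length(cols)] else character()
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  empty <- sv_callset(
    data.table(id = character(), chrom = character(), start = integer(),
               end = integer(), svtype = character(), length_bp = integer(),
               qual = numeric()),
    matrix(integer(), 0, length(samples), dimnames = list(NULL, samples)))
  if (length(body) == 0) {
    attr(empty, "skipped") <- 0L
    return(empty)
  }
  fields <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  info <- fields[[8]]
  get_info <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(^|;)", key, "="), info)
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  svtype <- get_info("SVTYPE")
  abort_if(anyNA(svtype),
           "record without SVTYPE at data line(s): ",
           paste(head(which(is.na(svtype)), 5), collapse = ", "))
  keep <- svtype %in% SV_TYPES
  skipped <- sum(!keep)
  if (!any(keep)) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  idx <- which(keep)
  pos <- as.integer(fields[[2]][idx])
  svlen <- suppressWarnings(as.numeric(get_info("SVLEN")[idx]))
  endi <- suppressWarnings(as.numeric(get_info("END")[idx]))
  len <- ifelse(is.na(svlen), endi - pos, abs(svlen))
  abort_if(anyNA(len), "record with neither SVLEN nor END")
  len <- as.integer(round(len))
  st <- svtype[idx]
  records <- data.table(
    id = fields[[3]][idx], chrom = fields[[1]][idx], start = pos,
    end = as.integer(ifelse(st == "INS", pos, pos + len - 1L)),
    svtype = st, length_bp = len,
    qual = suppressWarnings(as.numeric(fields[[6]][idx])))
  sup <- get_info("SUPP")[idx]
  if (!all(is.na(sup))) records[, support := as.integer(sup)]
  gt <- matrix(NA_integer_, length(idx), length(samples),
               dimnames = list(records$id, samples))
  if (length(samples)) {
    for (j in seq_along(samples)) {
      gt[, j] <- gt_to_code(fields[[9L + j]][idx])
    }
  }
  out <- sv_callset(records, gt)
  attr(out, "skipped") <- skipped
  out
}

#' Write an SV call set (or genotype matrix) as VCF 4.2
#'
#' Serialises records with `SVTYPE`, `SVLEN` (negative for deletions, caller
#' convention), `END = POS + length_bp` and, when present, `SUPP` in INFO;
#' genotypes as `GT`. Round-trips through [read_sv_vcf()] exactly.
#'
#' @param x a [sv_callset()] or [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(x, path) {
  if (inherits(x, "genotype_matrix")) {
    x <- sv_callset(x$sites, x$codes)
  }
  r <- x$records
  samples <- colnames(x$gt)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svscape",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
           '##INFO=<ID=SUPP,Number=1,Type=Integer,Description="Supporting samples">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  if (nrow(r) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  svlen <- ifelse(r$svtype == "DEL", -r$length_bp, r$length_bp)
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", r$svtype, svlen,
                  r$start + r$length_bp)
  if ("support" %in% names(r)) {
    info <- paste0(info, ";SUPP=", r$support)
  }
  gt_txt <- apply(x$gt, 1L, function(row) paste(code_to_gt(row), collapse = "\t"))
  body <- sprintf("%s\t%d\t%s\tN\t<%s>\t%s\tPASS\t%s\tGT\t%s",
                  r$chrom, r$start, r$id, r$svtype,
                  format(r$qual, trim = TRUE), info, gt_txt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Merge SV call sets
#'
#' Greedy transitive chaining in `(chrom, start)` order, the desk-scale
#' counterpart of multi-caller SV merging at distance 50: calls on the same
#' chromosome, of the same type (when `require_type_match`), whose start --
#' and, for non-insertions, end -- both lie within `max_dist_bp` of the
#' cluster seed (the first call of the chain) are merged. Representative
#' coordinates are per-coordinate medians of the members; `support` counts
#' distinct contributing samples; merged sets with `support < min_support`
#' are dropped. Output is sorted by `(chrom, start)`.
#'
#' @param callsets non-empty list of [sv_callset()] objects sharing a
#'   coordinate system.
#' @param max_dist_bp maximum breakpoint distance to the chain seed.
#' @param require_type_match merge only calls of identical `svtype`.
#' @param min_support minimum number of distinct supporting samples.
#' @return A merged [sv_callset()] whose genotype matrix covers the union of
#'   input samples (`NA` where a sample contributed no call) and whose
#'   `members` attribute records, per merged id, the contributing calls.
#' @export
merge_callsets <- function(callsets, max_dist_bp = 50L,
                           require_type_match = TRUE, min_support = 1L) {
  abort_if(length(callsets) == 0, "empty call-set list")
  abort_if(!all(vapply(callsets, inherits, TRUE, "sv_callset")),
           "all inputs must be sv_callset objects")
  pool <- rbindlist(lapply(seq_along(callsets), function(i) {
    cs <- callsets[[i]]
    if (nrow(cs$records) == 0) return(NULL)
    single <- ncol(cs$gt) == 1L
    mask <- attr(cs, "member_mask")
    per_sample <- lapply(colnames(cs$gt), function(s) {
      # in a single-sample file every record (incl. ./.) belongs to the
      # sample; in an already-merged set the member mask says who called what;
      # otherwise NA means the sample has no member call
      member <- if (single) rep(TRUE, nrow(cs$records))
                else if (!is.null(mask)) mask[, s]
                else !is.na(cs$gt[, s])
      if (!any(member)) return(NULL)
      dt <- cs$records[member, .(id, chrom, start, end, svtype, length_bp, qual)]
      dt[, sample := s]
      dt[, gt := cs$gt[member, s]]
      dt[, src := i]
      dt
    })
    rbindlist(per_sample)
  }))
  all_samples <- unique(unlist(lapply(callsets, function(cs) colnames(cs$gt))))
  if (is.null(pool) || nrow(pool) == 0) {
    return(sv_callset(
      data.table(id = character(), chrom = character(), start = integer(),
                 end = integer(), svtype = character(), length_bp = integer(),
                 qual = numeric(), support = integer()),
      matrix(integer(), 0, length(all_samples),
             dimnames = list(NULL, all_samples))))
  }
  pool[, ord := .I]
  grp_cols <- if (require_type_match) c("chrom", "svtype") else "chrom"
  setorderv(pool, c(grp_cols, "start", "ord"))
  # seed-anchored chaining within each (chrom[, svtype]) group
  pool[, cluster := {
    n <- .N
    cl <- integer(n)
    cid <- 0L
    seed_start <- -1e18; seed_end <- -1e18; seed_ins <- FALSE
    for (k in seq_len(n)) {
      ins <- svtype[k] == "INS"
      joins <- cid > 0L &&
        abs(start[k] - seed_start) <= max_dist_bp &&
        (ins || abs(end[k] - seed_end) <= max_dist_bp)
      if (!joins) {
        cid <- cid + 1L
        seed_start <- start[k]; seed_end <- end[k]
      }
      cl[k] <- cid
    }
    cl
  }, by = grp_cols]
  pool[, cluster_id := paste(do.call(paste, c(.SD, sep = "|")), cluster,
                             sep = "|"), .SDcols = grp_cols]
  imed <- function(x) as.integer(floor(median(x)))
  merged <- pool[, {
    ins <- svtype[1L] == "INS"
    rep_start <- imed(start)
    rep_len <- max(1L, imed(length_bp))
    .(id = names(sort(table(id), decreasing = TRUE))[1L],
      chrom = chrom[1L],
      start = rep_start,
      end = if (ins) rep_start else rep_start + rep_len - 1L,
      svtype = svtype[1L],
      length_bp = rep_len,
      qual = max(qual),
      support = uniqueN(sample))
  }, by = cluster_id]
  merged <- merged[support >= min_support]
  setorder(merged, chrom, start)
  merged[, id := make.unique(id, sep = "_dup")]
  # genotype per sample: the first member call contributed by that sample;
  # member_mask distinguishes "member with ./." from "no member at all"
  first_gt <- pool[cluster_id %in% merged$cluster_id,
                   .SD[1L], by = .(cluster_id, sample)]
  gt <- matrix(NA_integer_, nrow(merged), length(all_samples),
               dimnames = list(NULL, all_samples))
  mask <- matrix(FALSE, nrow(merged), length(all_samples),
                 dimnames = list(merged$id, all_samples))
  ridx <- match(first_gt$cluster_id, merged$cluster_id)
  cidx <- match(first_gt$sample, all_samples)
  keep_gt <- !is.na(ridx)
  gt[cbind(ridx[keep_gt], cidx[keep_gt])] <- first_gt$gt[keep_gt]
  mask[cbind(ridx[keep_gt], cidx[keep_gt])] <- TRUE
  members <- split(pool[cluster_id %in% merged$cluster_id,
                        .(cluster_id, id, sample, start, end, gt, qual)],
                   by = "cluster_id", keep.by = FALSE)
  names(members) <- merged$id[match(names(members), merged$cluster_id)]
  merged[, cluster_id := NULL]
  out <- sv_callset(merged, gt)
  attr(out, "members") <- members
  attr(out, "member_mask") <- mask
  out
}

#' Genotype matrix container
#'
#' @param codes integer matrix (SVs x samples) of alternate-allele counts
#'   `{0, 1, 2, NA}`.
#' @param sites data.frame of per-SV site information (`id, chrom, start, end,
#'   svtype, length_bp, qual`, optionally `support`), one row per matrix row.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, sites) {
  sites <- as.data.table(sites)
  codes <- as.matrix(codes)
  abort_if(nrow(sites) != nrow(codes), "sites/codes row mismatch")
  abort_if(anyDuplicated(sites$id) > 0, "duplicate SV ids")
  ok <- codes %in% c(0L, 1L, 2L) | is.na(codes)
  abort_if(!all(ok), "genotype codes must be 0/1/2/NA")
  rownames(codes) <- sites$id
  structure(list(codes = codes, sites = sites), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$codes), "SVs x", ncol(x$codes), "samples\n")
  invisible(x)
}

#' Expand a merged call set to a full genotype matrix
#'
#' Samples that contributed a member call keep their genotype; samples without
#' one receive the absent-genotype policy. The default `hom_ref` mirrors
#' re-genotyping every sample at merged breakpoints (a sample in which the
#' caller saw nothing is treated as homozygous reference); `missing` is the
#' conservative alternative.
#'
#' @param merged a merged [sv_callset()].
#' @param sample_ids superset of the samples present in `merged`.
#' @param absent `"hom_ref"` or `"missing"`.
#' @return A [genotype_matrix()].
#' @export
to_genotype_matrix <- function(merged, sample_ids,
                               absent = c("hom_ref", "missing")) {
  absent <- match.arg(absent)
  abort_if(!all(colnames(merged$gt) %in% sample_ids),
           "sample_ids must cover every sample in the merged set")
  abort_if(anyDuplicated(merged$records$id) > 0, "duplicate SV ids")
  fill <- if (absent == "hom_ref") 0L else NA_integer_
  codes <- matrix(fill, nrow(merged$records), length(sample_ids),
                  dimnames = list(merged$records$id, sample_ids))
  mask <- attr(merged, "member_mask")
  for (s in colnames(merged$gt)) {
    v <- merged$gt[, s]
    seen <- !is.na(v)
    codes[seen, s] <- v[seen]
    if (!is.null(mask)) {
      # a member call carrying ./. stays missing under either policy
      codes[mask[, s] & !seen, s] <- NA_integer_
    }
  }
  genotype_matrix(codes, merged$records)
}

#' Filter a genotype matrix
#'
#' Desk-scale equivalent of the standard site filters
#' `--max-missing 0.5 --mac 3 --minQ 30`: retain sites whose call rate is at
#' least `max_missing` (the tool's flag names a minimum call-rate), whose
#' minor allele count over called genotypes is at least `mac`, and whose site
#' quality is at least `min_qual`.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing minimum fraction of called genotypes (0 = no filter).
#' @param mac minimum minor allele count.
#' @param min_qual minimum site quality.
#' @return The filtered [genotype_matrix()]; attribute `filter_stats` counts
#'   sites removed by each rule (a site may fail several).
#' @export
filter_callset <- function(gm, max_missing = 0.5, mac = 3L, min_qual = 30) {
  abort_if(!inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  called <- rowMeans(!is.na(gm$codes))
  ac <- rowSums(gm$codes, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(gm$codes))
  minor <- pmin(ac, an - ac)
  qual <- gm$sites$qual
  pass_rate <- called >= max_missing
  pass_mac <- minor >= mac
  pass_q <- !is.na(qual) & qual >= min_qual
  keep <- pass_rate & pass_mac & pass_q
  out <- genotype_matrix(gm$codes[keep, , drop = FALSE], gm$sites[keep])
  attr(out, "filter_stats") <- c(n_in = nrow(gm$codes), n_out = sum(keep),
                                 fail_call_rate = sum(!pass_rate),
                                 fail_mac = sum(!pass_mac),
                                 fail_qual = sum(!pass_q))
  out
}

#' Read / write a sample-to-population map
#'
#' Two-column tab-separated file `sample<TAB>population`, no header.
#'
#' @param path file path.
#' @return `read_population_map`: data.table `sample, population`.
#' @export
read_population_map <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("sample", "population"),
              colClasses = "character")
  dt
}

#' @param popmap data.frame with columns `sample, population`.
#' @rdname read_population_map
#' @export
write_population_map <- function(popmap, path) {
  fwrite(as.data.table(popmap)[, .(sample, population)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}
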