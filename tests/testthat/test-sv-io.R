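make_vcf_fixture <- function(lines_body, samples = "s1") {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines_body), path)
  path
}

test_that("read_sv_vcf parses the SV dialect and skips non-SV types", {
  path <- make_vcf_fixture(c(
    "chr1\t1000\td1\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;SVLEN=-120;END=1120\tGT\t0/1",
    "chr1\t5000\ti1\tN\t<INS>\t50\tPASS\tSVTYPE=INS;SVLEN=75\tGT\t1/1",
    "chr2\t9000\tv1\tN\t<INV>\t40\tPASS\tSVTYPE=INV;END=9500\tGT\t0/1",
    "chr2\t20000\tb1\tN\tN[chr3:1[\t30\tPASS\tSVTYPE=BND\tGT\t0/1"))
  cs <- read_sv_vcf(path)
  expect_equal(nrow(cs$records), 3)
  expect_equal(cs$records$length_bp, c(120L, 75L, 500L))
  expect_equal(cs$records$svtype, c("DEL", "INS", "INV"))
  expect_equal(attr(cs, "skipped"), 1L)
  expect_equal(cs$records[svtype == "INS", end],
               cs$records[svtype == "INS", start])
  expect_equal(unname(cs$gt[, "s1"]), c(1L, 2L, 1L))
})

test_that("header-only VCF gives an empty call set", {
  path <- make_vcf_fixture(character())
  cs <- read_sv_vcf(path)
  expect_equal(nrow(cs$records), 0)
  expect_equal(attr(cs, "skipped"), 0L)
})

test_that("a retained record without SVTYPE is a parse error", {
  path <- make_vcf_fixture(
    "chr1\t1000\tx\tN\t<DEL>\t60\tPASS\tSVLEN=-120;END=1120\tGT\t0/1")
  expect_error(read_sv_vcf(path), "SVTYPE")
  expect_error(read_sv_vcf(file.path(tempdir(), "nope.vcf")), "cannot read")
})

test_that("VCF write/read round-trips a genotype matrix exactly", {
  co <- small_cohort()$cohort
  merged <- merge_callsets(co$callsets)
  gm <- to_genotype_matrix(merged, co$popmap$sample)
  sub <- genotype_matrix(gm$codes[1:5, , drop = FALSE], gm$sites[1:5])
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(sub, path)
  back <- read_sv_vcf(path)
  expect_equal(back$records[, .(id, chrom, start, end, svtype, length_bp)],
               sub$sites[, .(id, chrom, start, end, svtype, length_bp)],
               ignore_attr = TRUE)
  expect_identical(unname(back$gt), unname(sub$codes))
  expect_equal(back$records$qual, sub$sites$qual)
})

test_that("merge combines calls within distance and respects type match", {
  mk <- function(id, chrom, start, end, svtype, len, sample) {
    sv_callset(
      data.table::data.table(id = id, chrom = chrom, start = start, end = end,
                             svtype = svtype, length_bp = len, qual = 60),
      matrix(1L, length(id), 1, dimnames = list(id, sample)))
  }
  # hand-checked: delta-start 30 <= 50, delta-end 20 <= 50 -> one record
  m <- merge_callsets(list(mk("a", "chr1", 1000L, 1200L, "DEL", 201L, "s1"),
                           mk("b", "chr1", 1030L, 1220L, "DEL", 191L, "s2")))
  expect_equal(nrow(m$records), 1)
  expect_equal(m$records$support, 2)
  expect_equal(m$records$start, 1015L)  # floor(median(1000, 1030))
  expect_equal(unname(m$gt[1, c("s1", "s2")]), c(1L, 1L))
  # type mismatch at identical position stays separate
  m2 <- merge_callsets(list(
    mk("a", "chr1", 1000L, 1000L, "INS", 100L, "s1"),
    mk("b", "chr1", 1000L, 1099L, "DEL", 100L, "s2")))
  expect_equal(nrow(m2$records), 2)
  # beyond max_dist stays separate
  m3 <- merge_callsets(list(mk("a", "chr1", 1000L, 1200L, "DEL", 201L, "s1"),
                            mk("b", "chr1", 1060L, 1260L, "DEL", 201L, "s2")))
  expect_equal(nrow(m3$records), 2)
  expect_error(merge_callsets(list()), "empty")
})

test_that("merging a single or already-merged set is a fixed point", {
  co <- small_cohort()$cohort
  one <- co$callsets[[1]]
  m1 <- merge_callsets(list(one))
  expect_equal(nrow(m1$records), nrow(one$records))
  expect_equal(m1$records$start[order(m1$records$id)],
               one$records$start[order(one$records$id)])
  merged <- merge_callsets(co$callsets)
  again <- merge_callsets(list(merged))
  expect_equal(nrow(again$records), nrow(merged$records))
  expect_identical(unname(again$gt[order(again$records$id),
                                   colnames(merged$gt)]),
                   unname(merged$gt[order(merged$records$id), ]))
})

test_that("merge never grows the record count and members obey the radius", {
  co <- small_cohort()$cohort
  n_in <- sum(vapply(co$callsets, function(cs) nrow(cs$records), 0L))
  merged <- merge_callsets(co$callsets)
  expect_lte(nrow(merged$records), n_in)
  members <- attr(merged, "members")
  expect_setequal(names(members), merged$records$id)
  for (id in sample(names(members), 25)) {
    mem <- members[[id]]
    seed <- mem[1]
    expect_true(all(abs(mem$start - seed$start) <= 50))
  }
})

test_that("absent-sample genotype policy is applied", {
  cs1 <- sv_callset(
    data.table::data.table(id = "a", chrom = "chr1", start = 100L, end = 199L,
                           svtype = "DEL", length_bp = 100L, qual = 50),
    matrix(1L, 1, 1, dimnames = list("a", "s1")))
  merged <- merge_callsets(list(cs1))
  gm <- to_genotype_matrix(merged, c("s1", "s2"))
  expect_equal(unname(gm$codes[1, ]), c(1L, 0L))
  gm2 <- to_genotype_matrix(merged, c("s1", "s2"), absent = "missing")
  expect_equal(unname(gm2$codes[1, ]), c(1L, NA_integer_))
  dup <- merged
  dup$records <- rbind(dup$records, dup$records)
  dup$gt <- rbind(dup$gt, dup$gt)
  expect_error(to_genotype_matrix(dup, c("s1", "s2")), "duplicate")
})

test_that("filter_callset applies call-rate, mac and quality rules", {
  codes <- rbind(
    c(1L, 1L, NA, NA, NA),   # 40% called -> fails 0.5 call-rate
    c(1L, 1L, 0L, 0L, 0L),   # mac 2 -> removed
    c(1L, 1L, 1L, 0L, 0L),   # mac 3 -> kept (boundary is >=)
    c(2L, 2L, 1L, 0L, 0L))   # mac 5 -> kept
  colnames(codes) <- sprintf("s%d", 1:5)
  gm <- toy_gm(codes)
  out <- filter_callset(gm)
  expect_equal(out$sites$id, c("sv003", "sv004"))
  # quality boundary
  gm_q <- toy_gm(codes[3:4, , drop = FALSE], qual = c(29.9, 30))
  out_q <- filter_callset(gm_q)
  expect_equal(nrow(out_q$codes), 1)
  # all passing -> identity
  gm_ok <- toy_gm(codes[3:4, , drop = FALSE])
  out_ok <- filter_callset(gm_ok)
  expect_identical(out_ok$codes, gm_ok$codes)
})
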