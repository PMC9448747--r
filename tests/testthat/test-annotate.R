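sv_row <- function(id, chrom, start, end, svtype = "DEL") {
  data.table::data.table(id = id, chrom = chrom, start = start, end = end,
                         svtype = svtype)
}

test_that("single-region overlaps land in the expected category", {
  m <- toy_models()
  # wholly inside gA intron (10300..10999)
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 10400L, 10500L), m)$category), "intronic")
  # DEL spanning CDS and intron -> exonic wins by priority
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 10900L, 11100L), m)$category), "exonic")
  # UTR overlap
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 10250L, 10350L), m)$category), "UTR")
})

test_that("strand-aware flank boundaries match their definitions", {
  m <- toy_models()
  # + strand gene gA: TSS = 10000
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 9900L, 9900L), m)$category), "upstream")
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 9500L, 9500L), m)$category), "promoter")
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 14099L, 14099L), m)$category),
    "downstream")
  # exact boundaries: promoter ends at TSS - 151, upstream at TSS - 1
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 9849L, 9849L), m)$category), "promoter")
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 9850L, 9850L), m)$category), "upstream")
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 9999L, 9999L), m)$category), "upstream")
  # - strand gene gB: TSS = 34000-1 = 33999, so promoter is to the right
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 34100L, 34100L), m)$category), "upstream")
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 34500L, 34500L), m)$category), "promoter")
  expect_equal(as.character(
    classify_svs(sv_row("s", "chr1", 29900L, 29900L), m)$category),
    "downstream")
  # far away -> intergenic with empty gene list
  far <- classify_svs(sv_row("s", "chr1", 500000L, 500100L), m)
  expect_equal(as.character(far$category), "intergenic")
  expect_equal(far$gene_ids, "")
})

test_that("insertions are evaluated at their insertion point", {
  m <- toy_models()
  # an INS whose [start, end-as-span] would touch the gene, but whose point
  # does not, must stay intergenic-side
  ins <- sv_row("s", "chr1", 7995L, 7995L, svtype = "INS")
  expect_equal(as.character(classify_svs(ins, m)$category), "intergenic")
  ins2 <- sv_row("s", "chr1", 11100L, 11100L, svtype = "INS")
  expect_equal(as.character(classify_svs(ins2, m)$category), "exonic")
})

test_that("deletion frameshift arithmetic follows the mod-3 rule", {
  m <- toy_models()
  # 50 bp wholly inside gA CDS -> 50 %% 3 = 2 -> frameshift
  a50 <- classify_svs(sv_row("s", "chr1", 11100L, 11149L), m)
  expect_equal(a50$coding_effect, "frameshift")
  # 51 bp -> inframe
  a51 <- classify_svs(sv_row("s", "chr1", 11100L, 11150L), m)
  expect_equal(a51$coding_effect, "inframe")
  # intron-only deletion -> none
  a0 <- classify_svs(sv_row("s", "chr1", 10400L, 10500L), m)
  expect_equal(a0$coding_effect, "none")
  # non-DEL types never get a coding effect
  inv <- classify_svs(sv_row("s", "chr1", 11100L, 11149L, "INV"), m)
  expect_equal(inv$coding_effect, "none")
  # the single-record API agrees
  expect_equal(coding_effect(list(chrom = "chr1", start = 11100L,
                                  end = 11149L, svtype = "DEL"), m),
               "frameshift")
  expect_equal(coding_effect(list(chrom = "chr1", start = 11100L,
                                  end = 11150L, svtype = "DEL"), m),
               "inframe")
})

test_that("every SV gets exactly one category and counts are exhaustive", {
  m <- toy_models()
  set.seed(42)
  n <- 400
  svs <- data.table::data.table(
    id = sprintf("r%04d", 1:n), chrom = "chr1",
    start = sample(7000:37000, n, replace = TRUE),
    svtype = sample(c("DEL", "INS", "DUP", "INV"), n, replace = TRUE))
  svs[, end := ifelse(svtype == "INS", start,
                      start + sample(50:500, n, replace = TRUE))]
  ann <- classify_svs(svs, m)
  expect_equal(nrow(ann), n)
  expect_false(anyNA(ann$category))
  expect_equal(sum(table(ann$category)), n)
  expect_true(all(as.character(ann$category) != "intergenic" |
                    ann$gene_ids == ""))
  expect_true(all(as.character(ann$category) == "intergenic" |
                    ann$gene_ids != ""))
})

test_that("indexed classifier agrees with the brute-force oracle", {
  m <- toy_models()
  set.seed(43)
  n <- 300
  svs <- data.table::data.table(
    id = sprintf("r%04d", 1:n), chrom = "chr1",
    start = sample(7000:37000, n, replace = TRUE),
    svtype = sample(c("DEL", "INS", "DUP", "INV"), n, replace = TRUE))
  svs[, end := ifelse(svtype == "INS", start,
                      start + sample(50:500, n, replace = TRUE))]
  ann <- classify_svs(svs, m)
  for (i in seq_len(n)) {
    o <- oracle_classify(as.list(svs[i]), m)
    expect_equal(as.character(ann$category[i]), o$category)
  }
})

test_that("reflecting coordinates and flipping strands preserves categories", {
  m <- toy_models()
  L <- 50000L
  refl_genes <- data.table::copy(m$genes)[
    , `:=`(tx_start = L + 1L - tx_end, tx_end = L + 1L - tx_start,
           strand = ifelse(strand == "+", "-", "+"))]
  refl_feat <- data.table::copy(m$features)[
    , `:=`(start = L + 1L - end, end = L + 1L - start)]
  # utr5/utr3 swap roles under reflection+flip (5' stays 5' biologically)
  refl_m <- gene_model_set(refl_genes, refl_feat)
  set.seed(44)
  n <- 150
  svs <- data.table::data.table(
    id = sprintf("r%04d", 1:n), chrom = "chr1",
    start = sample(7000:37000, n, replace = TRUE),
    svtype = sample(c("DEL", "INS", "INV"), n, replace = TRUE))
  svs[, end := ifelse(svtype == "INS", start,
                      start + sample(50:400, n, replace = TRUE))]
  refl_svs <- data.table::copy(svs)[
    , `:=`(start = L + 1L - end, end = L + 1L - start)]
  refl_svs[svtype == "INS", `:=`(start = end)]
  a1 <- classify_svs(svs, m)
  a2 <- classify_svs(refl_svs, refl_m)
  expect_equal(as.character(a1$category), as.character(a2$category))
})

test_that("gene_category_lists reproduces exhaustive set algebra", {
  ann <- data.table::data.table(
    sv_id = sprintf("v%d", 1:6),
    category = factor(c("exonic", "promoter", "intronic", "UTR",
                        "intergenic", "downstream"),
                      levels = svscape:::CATEGORY_LEVELS),
    gene_ids = c("g1", "g2", "g2,g3", "g3", "", "g4"),
    coding_effect = "none")
  high <- c("v1", "v2", "v3", "v5", "v6")
  out <- gene_category_lists(ann, high)
  # oracle by enumeration: non-intergenic high-FST SVs touch g1,g2,g3,g4;
  # exonic/promoter ones touch g1,g2
  expect_setequal(out$list1, c("g1", "g2", "g3", "g4"))
  expect_setequal(out$list2, c("g1", "g2"))
  expect_true(all(out$list2 %in% out$list1))
  empty <- gene_category_lists(ann, character())
  expect_length(empty$list1, 0)
  expect_length(empty$list2, 0)
  expect_error(gene_category_lists(ann, "nope"), "cover")
})
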