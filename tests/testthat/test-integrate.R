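test_that("chi-square association matches the closed form on a hand table", {
  universe <- sprintf("g%03d", 1:100)
  degs <- universe[1:50]
  svs <- universe[1:50]
  res <- chi_square_association(universe, degs, svs)
  # chi2 = N (ad - bc)^2 / (r1 r2 c1 c2) = 100 * (50*50)^2 / 50^4 = 100
  expect_equal(res$chi2, 100)
  expect_equal(res$df, 1)
  expect_lt(res$p, 1e-20)
  expect_equal(unclass(res$table)[1, 1], 50)
  # symmetry in the two set arguments
  degs2 <- universe[30:60]; svs2 <- universe[45:90]
  r1 <- chi_square_association(universe, degs2, svs2)
  r2 <- chi_square_association(universe, svs2, degs2)
  expect_equal(r1$chi2, r2$chi2)
  expect_equal(r1$p, r2$p)
  expect_error(chi_square_association(universe, character(), svs),
               "degenerate margin")
  expect_error(chi_square_association(universe, degs, c("zzz")), "subset")
})

test_that("chi-square p-values are uniform under independent random sets", {
  set.seed(12)
  universe <- sprintf("g%04d", 1:1000)
  ps <- replicate(200, {
    degs <- sample(universe, 200)
    svs <- sample(universe, 150)
    suppressWarnings(chi_square_association(universe, degs, svs)$p)
  })
  # ks.test warns about ties (p-values are discrete); the test is still valid
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("venn_counts covers identity, disjoint and random cases", {
  ids <- sprintf("g%02d", 1:30)
  same <- venn_counts(ids[1:10], ids[1:10], ids[1:10])
  expect_equal(unname(same["111"]), 10)
  expect_equal(sum(same), 10)
  disj <- venn_counts(ids[1:5], ids[6:12], ids[13:20])
  expect_equal(unname(disj[c("100", "010", "001")]), c(5, 7, 8))
  expect_equal(sum(disj[c("110", "101", "011", "111")]), 0)
  set.seed(13)
  l1 <- sample(ids, 12); l2 <- sample(ids, 9); l3 <- sample(ids, 15)
  v <- venn_counts(l1, l2, l3)
  expect_equal(sum(v), length(unique(c(l1, l2, l3))))
  # enumeration oracle for one region
  expect_equal(unname(v["110"]),
               sum(ids %in% l1 & ids %in% l2 & !(ids %in% l3)))
  expect_equal(unname(v["011"]),
               sum(!(ids %in% l1) & ids %in% l2 & ids %in% l3))
})

test_that("marker_enrichment ratios, Fisher p and normalisation behave", {
  mt <- data.table::data.table(
    cluster = rep(1:3, c(5, 5, 4)),
    gene_id = sprintf("g%02d", c(1:5, 6:10, 11:14)))
  universe <- sprintf("g%02d", 1:20)
  # saturation: list == universe
  sat <- marker_enrichment(mt, list(all = universe), universe)
  expect_equal(sat$ratio, rep(1, 3))
  expect_equal(sat$fisher_p, rep(1, 3))
  # disjoint list
  disj <- marker_enrichment(mt, list(none = sprintf("g%02d", 15:20)),
                            universe)
  expect_equal(disj[cluster == "1", ratio], 0)
  # hand case: universe 20, M = 5, L = 8, overlap 4 vs enumeration oracle
  lst <- sprintf("g%02d", c(1:4, 11:14))
  res <- marker_enrichment(mt, list(L = lst), universe)
  tab <- matrix(c(4, 1, 4, 11), 2, 2, byrow = TRUE)
  expect_equal(res[cluster == "1", fisher_p], oracle_fisher_two_sided(tab))
  expect_equal(res[cluster == "1", ratio], 4 / 5)
  # normalised ratio: mean 0, sd 1 across clusters within a list
  expect_equal(mean(res$normalized_ratio), 0, tolerance = 1e-12)
  expect_equal(sd(res$normalized_ratio), 1, tolerance = 1e-12)
  # zero-marker cluster: NA row plus warning
  mt0 <- rbind(mt, data.table::data.table(cluster = 4, gene_id = "zzz"))
  expect_warning(res0 <- marker_enrichment(mt0, list(L = lst), universe),
                 "zero markers")
  expect_true(is.na(res0[cluster == "4", ratio]))
})

test_that("fisher_p equals hypergeometric enumeration on random tables", {
  set.seed(14)
  universe <- sprintf("u%02d", 1:40)
  for (rep in 1:20) {
    m_size <- sample(2:15, 1)
    l_size <- sample(2:25, 1)
    markers <- sample(universe, m_size)
    lst <- sample(universe, l_size)
    mt <- data.table::data.table(cluster = 1, gene_id = markers)
    res <- marker_enrichment(mt, list(L = lst), universe)
    ov <- length(intersect(markers, lst))
    tab <- matrix(c(ov, m_size - ov, l_size - ov,
                    40 - m_size - l_size + ov), 2, 2, byrow = TRUE)
    expect_equal(res$fisher_p, oracle_fisher_two_sided(tab),
                 tolerance = 1e-10)
  }
})

test_that("one_vs_rest_ratio_test matches t.test and handles edge cases", {
  mt <- data.table::data.table(
    cluster = rep(1:3, each = 20),
    gene_id = sprintf("g%03d", 1:60))
  # cluster 1 fully in the list, rest entirely out
  lst <- sprintf("g%03d", 1:20)
  res <- one_vs_rest_ratio_test(mt, lst, 1)
  expect_lt(res$p, 1e-6)
  expect_equal(res$prop_cluster, 1)
  expect_equal(res$prop_rest, 0)
  # equal membership rates: t = 0, p = 1
  lst_eq <- sprintf("g%03d", c(1:10, 21:30, 41:50))
  res_eq <- one_vs_rest_ratio_test(mt, lst_eq, 1)
  expect_equal(res_eq$t, 0)
  expect_equal(res_eq$p, 1)
  # hand Welch check against stats::t.test on the indicators
  set.seed(15)
  lst_r <- sample(mt$gene_id, 25)
  res_r <- one_vs_rest_ratio_test(mt, lst_r, 2)
  x <- as.integer(mt[cluster == 2, gene_id] %in% lst_r)
  y <- as.integer(mt[cluster != 2, gene_id] %in% lst_r)
  ref <- t.test(x, y)
  expect_equal(res_r$t, unname(ref$statistic))
  expect_equal(res_r$df, unname(ref$parameter))
  expect_equal(res_r$p, ref$p.value)
  # single-marker cluster errors
  mt1 <- rbind(mt, data.table::data.table(cluster = 9, gene_id = "solo"))
  expect_error(one_vs_rest_ratio_test(mt1, lst, 9), ">= 2 markers")
})
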