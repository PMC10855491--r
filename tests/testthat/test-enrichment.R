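test_that("hypergeometric upper tail matches hand enumeration and edge cases", {
  expect_equal(hypergeom_upper_tail(10, 5, 4, 0)$p, 1.0)
  expect_equal(hypergeom_upper_tail(10, 5, 4, 4)$p, 5 / 210, tolerance = 1e-12)
  # degenerate: sample is whole universe
  expect_equal(hypergeom_upper_tail(20, 7, 20, 7)$p, 1.0)
  expect_error(hypergeom_upper_tail(10, 5, 4, 5), "outside support")
  expect_error(hypergeom_upper_tail(10, 11, 4, 2), "K <= N")
})

test_that("log-space tail agrees with phyper across scales, including underflow", {
  set.seed(8)
  for (i in 1:50) {
    N <- sample(50:5000, 1); K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    ours <- hypergeom_upper_tail(N, K, n, k)
    ref <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
    expect_lt(abs(ours$log_p - ref), 1e-8 + 1e-9 * abs(ref))
  }
  # a genome-scale call far below double underflow still yields finite log p
  big <- hypergeom_upper_tail(48149, 27091, 7410, 7410)
  expect_true(is.finite(big$log_p) && big$log_p < -2000)
})

test_that("rank-sum exact p-values match full enumeration on the worked cases", {
  r1 <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r1$W, 0)
  expect_equal(r1$p, 2 / 6, tolerance = 1e-12)
  expect_equal(r1$method, "exact")
  r2 <- rank_sum_test(c(1, 4), c(2, 3))
  expect_equal(r2$W, 2)
  expect_equal(r2$p, 1)
  # one-sided enumeration: x entirely above y, C(4,2) arrangements
  r3 <- rank_sum_test(c(300, 400), c(100, 200), alternative = "greater")
  expect_equal(r3$p, 1 / 6, tolerance = 1e-12)
})

test_that("identical samples give a central statistic and p near 1", {
  x <- c(2, 2, 5, 9, 9, 1)
  r <- rank_sum_test(x, x)
  expect_equal(r$W, r$n1 * r$n2 / 2)
  expect_equal(r$p, 1)
  expect_equal(r$method, "normal_approx")  # ties force the approximation
})

test_that("rank-sum statistic and approximate p agree with wilcox.test", {
  set.seed(21)
  for (i in 1:20) {
    x <- stats::rnorm(sample(25:60, 1)); y <- stats::rnorm(sample(25:60, 1), 0.4)
    ours <- rank_sum_test(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(ours$W, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  # tied integer data exercises the tie-corrected variance
  for (i in 1:10) {
    x <- sample(0:4, 40, TRUE); y <- sample(0:5, 50, TRUE)
    ours <- rank_sum_test(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(ours$W, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("group summaries compute counts, percentage, and mean per the report conventions", {
  assignments <- data.frame(
    region_id = paste0("g", 1:4), region_class = "promoter",
    oq_count = c(0L, 2L, 1L, 0L))
  de <- stratify_de(data.frame(gene_id = paste0("g", 1:4),
                               log2fc = c(2, 2, 0, 0),
                               pvalue = 0.01, padj = c(0.01, 0.01, 0.5, 0.5)))
  part <- partition_genes(de, paste0("g", 1:4))
  sm <- summarize_oq_content(assignments, part, "promoter",
                             groups = c("all", "DE"))
  all_row <- sm[sm$group == "all", ]
  expect_equal(all_row$n_with_oq, 2L)
  expect_equal(all_row$pct_with_oq, 50.0)
  expect_equal(all_row$mean_oq_per_oq_region, 1.50)
  de_row <- sm[sm$group == "DE", ]
  expect_equal(de_row$n_regions, 2L)
  expect_equal(de_row$n_with_oq, 1L)
  # unknown region ids are an error when not silently restricted
  part2 <- partition_genes(de, paste0("g", 1:5))
  expect_error(summarize_oq_content(assignments, part2, "promoter",
                                    groups = "nonDE",
                                    restrict_to_regions = FALSE),
               "unknown region ids.*g5")
})

test_that("presence enrichment uses the region universe as background", {
  assignments <- data.frame(
    region_id = paste0("g", 1:10), region_class = "promoter",
    oq_count = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 1L))
  # log2fc below the 2-fold boundary keeps DE_2FC empty, so nonDE_2FC is
  # the whole universe
  de <- stratify_de(data.frame(gene_id = paste0("g", 1:10),
                               log2fc = 0.5, pvalue = 0.01,
                               padj = c(rep(0.01, 4), rep(0.5, 6))))
  part <- partition_genes(de, paste0("g", 1:10))
  res <- presence_enrichment(assignments, part, "promoter", "DE")
  expect_equal(c(res$N, res$K, res$n, res$k), c(10, 5, 4, 4))
  expect_equal(res$p, enum_hyper_upper(10, 5, 4, 4), tolerance = 1e-12)
  # group = universe degenerates to k = K, p = 1
  res_all <- presence_enrichment(assignments, part, "promoter", "nonDE_2FC")
  expect_equal(res_all$n, 10)
  expect_equal(res_all$p, 1)
})

test_that("count comparison restricts to OQ-containing regions by default", {
  assignments <- data.frame(
    region_id = paste0("g", 1:6), region_class = "promoter",
    oq_count = c(2L, 2L, 3L, 1L, 1L, 0L))
  de <- stratify_de(data.frame(gene_id = paste0("g", 1:6), log2fc = 2,
                               pvalue = 0.01,
                               padj = c(rep(0.01, 3), rep(0.5, 3))))
  part <- partition_genes(de, paste0("g", 1:6))
  res <- count_comparison(assignments, part, "promoter", "DE", "nonDE",
                          alternative = "greater")
  expect_equal(res$n2, 2L)  # the zero-count nonDE promoter is excluded
  # identical count vectors give p ~ 1
  same <- data.frame(region_id = paste0("g", 1:6), region_class = "promoter",
                     oq_count = rep(c(1L, 2L, 3L), 2))
  expect_gte(count_comparison(same, part, "promoter", "DE", "nonDE")$p, 0.99)
  none <- data.frame(region_id = paste0("g", 1:6), region_class = "promoter",
                     oq_count = c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_error(count_comparison(none, part, "promoter", "DE", "nonDE"),
               "no OQ-containing region")
})

test_that("length comparison flags the gene-length confound", {
  genes <- gr0("c1", c(0, 2000, 6000, 12000), c(1000, 5000, 11000, 19000),
               strand = "+", id = paste0("g", 1:4))
  assignments <- data.frame(region_id = paste0("g", 1:4),
                            region_class = "gene", oq_count = 1L)
  de <- stratify_de(data.frame(gene_id = paste0("g", 1:4), log2fc = 2,
                               pvalue = 0.01,
                               padj = c(0.5, 0.5, 0.01, 0.01)))
  part <- partition_genes(de, paste0("g", 1:4))
  lc <- length_comparison(genes, assignments, part, alternative = "greater")
  expect_equal(lc$mean_length_a, mean(c(5000, 7000)))
  expect_equal(lc$mean_length_b, mean(c(1000, 3000)))
  expect_equal(lc$ranksum$p, 1 / 6, tolerance = 1e-12)  # enumeration C(4,2)
})

test_that("over-representation applies BH and reconciles to the universe", {
  universe <- paste0("g", 1:20)
  terms <- list(t1 = paste0("g", 1:5), t2 = paste0("g", 6:10),
                t3 = c(paste0("g", 11:12), "not_in_universe"))
  query <- paste0("g", c(1:4, 6))
  res <- ora_with_bh(terms, query, universe)
  expect_equal(res$K[res$term == "t3"], 2)  # foreign id dropped
  expect_equal(res$k[res$term == "t1"], 4)
  # independent step-up oracle: adjusted_i = min_{j >= i} p_(j) * m / j
  bh_hand <- function(p) {
    m <- length(p); o <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    adj[order(o)]
  }
  expect_equal(res$padj, bh_hand(res$p), tolerance = 1e-12)
  expect_true(all(res$padj >= res$p))
  expect_true(all(diff(res$padj[order(res$p)]) >= 0))  # monotone in rank order
  # term disjoint from query: k = 0, p = 1
  res0 <- ora_with_bh(list(t = paste0("g", 15:18)), query, universe)
  expect_equal(res0$k, 0); expect_equal(res0$p, 1)
  # single term: adjusted equals raw
  res1 <- ora_with_bh(list(t = paste0("g", 1:5)), query, universe)
  expect_equal(res1$padj, res1$p)
  expect_error(ora_with_bh(terms, "absent", universe), "query is empty")
})
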