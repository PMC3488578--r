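test_that("gene-to-region assignment uses the any-overlap rule", {
  regions <- data.frame(chromosome = "1", cytoband = "x", start = 1000,
                        end = 2000, direction = "gain", freq_pct = 70,
                        n_clones = 5L, gene_n = NA_integer_)
  genes <- gene_table(c("IN", "EDGE", "OUT"), "1",
                      c(1200, 500, 2501), c(1400, 1000, 3000))
  res <- genes_in_regions(regions, genes)
  expect_setequal(res$genes$symbol, c("IN", "EDGE"))  # 1 bp overlap counts
  expect_equal(res$counts, 2L)
  expect_equal(unique(res$genes$direction), "gain")
  # empty gene table -> zero counts; row order does not matter
  expect_equal(genes_in_regions(regions, genes[0, ])$counts, 0L)
  perm <- genes_in_regions(regions, genes[c(3, 1, 2), ])
  expect_equal(perm$counts, res$counts)
  expect_setequal(perm$genes$symbol, res$genes$symbol)
})

test_that("hypergeometric upper tail matches direct enumeration", {
  expect_equal(hypergeometric_p(0, 3, 4, 10), 1)
  expect_equal(hypergeometric_p(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeometric_p(1, 2, 2, 4), 5 / 6, tolerance = 1e-12)
  # exhaustive check over a modest universe; the full N <= 12 sweep runs
  # in the acceptance suite
  for (N in 1:9) for (K in 0:N) for (n in 0:N) for (x in 0:min(K, n)) {
    expect_equal(hypergeometric_p(x, K, n, N), hyper_tail_oracle(x, K, n, N),
                 tolerance = 1e-12)
  }
  # monotone non-increasing in x
  ps <- vapply(0:4, function(x) hypergeometric_p(x, 6, 4, 12), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeometric_p(3, 2, 5, 10), "x <= min")
  expect_error(hypergeometric_p(1, 2, 5, 4), "<= N")
})

test_that("concordance filter keeps direction-consistent genes only", {
  genes <- gene_table(c("g1", "g2", "g3", "g4"), "1",
                      c(1, 1, 1, 1), c(2, 2, 2, 2))
  genes$direction <- c("gain", "gain", "loss", "loss")
  expr <- data.frame(symbol = c("g1", "g2", "g3"), ratio = c(2.0, 0.5, 0.5))
  expect_message(out <- concordance_filter(genes, expr), "1 gene")
  expect_setequal(out$symbol, c("g1", "g3"))
  expect_equal(attr(out, "n_no_expression"), 1L)
})

test_that("the selection funnel is monotone and hand-traceable", {
  regions <- data.frame(chromosome = "1", cytoband = "x", start = 1000,
                        end = 10000, direction = "gain", freq_pct = 70,
                        n_clones = 5L, gene_n = NA_integer_)
  # 20 genes: 10 inside the region, 10 elsewhere
  genes <- gene_table(sprintf("g%02d", 1:20), "1",
                      c(seq(1000, 9100, length.out = 10), seq(20000, 29000, length.out = 10)),
                      c(seq(1500, 9600, length.out = 10), seq(20500, 29500, length.out = 10)))
  genes$known_in_lung_cancer <- genes$symbol %in% c("g01", "g05")
  # one set holding 8 of the 10 region genes (enriched), one spread set
  gene_sets <- rbind(
    data.frame(set = "enriched", symbol = sprintf("g%02d", 1:8)),
    data.frame(set = "flat", symbol = sprintf("g%02d", c(1, 5, 11, 15, 18)))
  )
  # half of the enriched region genes concordant
  expr <- data.frame(symbol = sprintf("g%02d", 1:20),
                     ratio = rep(c(2, 0.5), 10))
  res <- select_candidates(regions, genes, gene_sets, expr, alpha = 0.05)
  # hand trace: stage1 = g01..g10 (10); "enriched" has x=8, K=8, n=10, N=20
  # (P = choose(12,2)/choose(20,10) small); "flat" x=2, K=5 not significant;
  # stage2 = g01..g08; concordant = odd-numbered (ratio 2, gain) -> 4
  expect_equal(res$funnel$count, c(10, 8, 4, 2))
  expect_setequal(res$candidates$symbol, c("g01", "g03", "g05", "g07"))
  expect_setequal(res$candidates$symbol[res$candidates$novel],
                  c("g03", "g07"))
  counts <- res$funnel$count
  expect_true(all(diff(counts) <= 0))
  # permissive and degenerate alphas
  res1 <- select_candidates(regions, genes, gene_sets, expr, alpha = 1.0)
  expect_equal(res1$funnel$count[1], 10)
  expect_equal(res1$funnel$count[2], 10)  # every set "significant" at alpha 1
  res0 <- select_candidates(regions, genes, gene_sets, expr, alpha = 0)
  expect_equal(res0$funnel$count[3], 0)
  expect_error(select_candidates(regions, genes[0, ], gene_sets, expr),
               "empty gene universe")
})
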