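test_that("clone frequencies count gains and losses with per-clone denominators", {
  calls <- list(vec_calls(c(1, 1, 0)), vec_calls(c(1, 1, 0)),
                vec_calls(c(1, -1, 0)), vec_calls(c(1, 0, NA)),
                vec_calls(c(1, 0, NA)))
  fr <- clone_frequencies(calls)
  expect_equal(fr$f_gain, c(1, 0.4, 0))
  expect_equal(fr$f_loss, c(0, 0.2, 0))
  expect_equal(fr$n_obs, c(5, 5, 3))
  expect_true(all(fr$f_gain + fr$f_loss <= 1))
  expect_error(clone_frequencies(list()), "empty cohort")
})

test_that("imbalance regions are maximal same-direction runs with median frequency", {
  f <- c(rep(0, 5), rep(0.7, 10), rep(0, 5))
  fr <- structure(data.frame(clone_id = sprintf("c%03d", 1:20),
                             chromosome = "1", start = 1:20 * 1000,
                             end = 1:20 * 1000 + 999, n_obs = 10,
                             f_gain = f, f_loss = 0),
                  class = c("cohort_freq", "data.frame"))
  reg <- call_imbalance_regions(fr, threshold_pct = 50)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$direction, "gain")
  expect_equal(reg$freq_pct, 70)
  expect_equal(reg$start, 6000)
  expect_equal(reg$end, 15999)
  expect_equal(reg$n_clones, 10)
  # all-zero frequencies give an empty table; min_clones suppresses singletons
  fr0 <- fr
  fr0$f_gain <- 0
  expect_equal(nrow(call_imbalance_regions(fr0)), 0)
  fr1 <- fr0
  fr1$f_gain[3] <- 0.9
  expect_equal(nrow(call_imbalance_regions(fr1, min_clones = 2)), 0)
  expect_equal(nrow(call_imbalance_regions(fr1, min_clones = 1)), 1)
})

test_that("region sizes in Mb round to two decimals", {
  expect_equal(region_size_mb(64934270, 73536726), 8.60)
  expect_equal(region_size_mb(5701499, 5872842), 0.17)
  expect_equal(region_size_mb(100, 100), 0.00)
})

test_that("common regions intersect by chromosome and direction", {
  mk <- function(chrom, start, end, dir, f) {
    data.frame(chromosome = chrom, cytoband = "x", start = start, end = end,
               direction = dir, freq_pct = f, n_clones = NA_integer_,
               gene_n = NA_integer_, stringsAsFactors = FALSE)
  }
  a <- mk("1", 100, 500, "gain", 70)
  b <- mk("1", 300, 900, "gain", 60)
  cm <- common_regions(a, b)
  expect_equal(nrow(cm), 1)
  expect_equal(c(cm$start, cm$end), c(300, 500))
  expect_equal(cm$freq_pct, 60)
  # symmetric up to coordinates, idempotent on identical inputs
  cm2 <- common_regions(b, a)
  expect_equal(cm[, c("chromosome", "start", "end", "direction")],
               cm2[, c("chromosome", "start", "end", "direction")])
  self <- common_regions(a, a)
  expect_equal(c(self$start, self$end), c(100, 500))
  # disjoint, direction-mismatched, or at-threshold rows drop out
  expect_equal(nrow(common_regions(a, mk("1", 600, 900, "gain", 70))), 0)
  expect_equal(nrow(common_regions(a, mk("1", 300, 900, "loss", 70))), 0)
  expect_equal(nrow(common_regions(a, mk("1", 300, 900, "gain", 50))), 0)
})

test_that("signed-frequency difference matches the printed convention", {
  expect_equal(signed_frequency_difference("loss", 25, "gain", 40), 65)
  expect_equal(signed_frequency_difference("gain", 50, "gain", 70), 20)
  expect_equal(signed_frequency_difference("loss", 60, "none", 0), 60)
  expect_equal(signed_frequency_difference("gain", 33, "gain", 33), 0)
  # symmetric and bounded
  expect_equal(signed_frequency_difference("gain", 80, "loss", 95),
               signed_frequency_difference("loss", 95, "gain", 80))
  expect_equal(signed_frequency_difference("gain", 100, "loss", 100), 200)
  expect_error(signed_frequency_difference("gain", 120, "gain", 10), "0, 100")
  expect_error(signed_frequency_difference("up", 10, "gain", 10), "direction")
})

test_that("every printed difference cell reproduces from its two group cells", {
  for (f in c("table2a.tsv", "table2b.tsv", "table3a.tsv", "table3b.tsv")) {
    d <- read_difference_table(cgh_fixture(f))
    D <- signed_frequency_difference(d$a_direction, d$a_freq_pct,
                                     d$b_direction, d$b_freq_pct)
    expect_equal(D, d$diff_pct, info = f)
  }
})

test_that("stratified comparison recovers a planted group difference", {
  # group A: 17 of 20 carry a loss on clones 6-15; group B: 6 of 20
  set.seed(31)
  mkc <- function(carrier) {
    s <- rep(0L, 20)
    if (carrier) s[6:15] <- -1L
    vec_calls(s)
  }
  calls <- c(lapply(seq_len(20), function(i) mkc(i <= 17)),
             lapply(seq_len(20), function(i) mkc(i <= 6)))
  meta <- data.frame(sample_id = sprintf("s%02d", 1:40),
                     subtype = rep(c("ADC", "SCC"), each = 20))
  ent <- stratified_differential_regions(calls, meta, "subtype", 50)
  expect_equal(nrow(ent), 1)
  expect_equal(ent$a_direction, "loss")
  expect_equal(ent$a_freq_pct, 85)
  expect_equal(ent$b_direction, "loss")
  expect_equal(ent$b_freq_pct, 30)
  expect_equal(ent$diff_pct, 55)
  expect_equal(c(ent$start, ent$end), c(6000, 15999))
  # identical groups: nothing at threshold 50, every run at threshold 0
  same <- c(lapply(1:4, function(i) mkc(TRUE)), lapply(1:4, function(i) mkc(TRUE)))
  meta2 <- data.frame(sample_id = sprintf("s%d", 1:8),
                      subtype = rep(c("ADC", "SCC"), each = 4))
  expect_equal(nrow(stratified_differential_regions(same, meta2, "subtype", 50)), 0)
  expect_gt(nrow(stratified_differential_regions(same, meta2, "subtype", 0)), 0)
  # a factor level with no samples is an error
  meta3 <- meta2
  meta3$subtype <- "ADC"
  expect_error(stratified_differential_regions(same, meta3, "subtype"), "2 observed levels")
})

test_that("region-table summaries add up the printed gene counts", {
  a <- read_region_table(cgh_fixture("table1a.tsv"))
  b <- read_region_table(cgh_fixture("table1b.tsv"))
  sa <- summarize_region_table(a)
  sb <- summarize_region_table(b)
  expect_equal(sa$total_gene_count, 476)
  expect_equal(sb$total_gene_count, 459)
  expect_equal(sa$n_regions, 17)
  expect_equal(sb$n_regions, 20)
  expect_equal(sa$n_gain, 8)
  expect_equal(sa$n_loss, 9)
  expect_equal(sb$n_gain, 11)
  expect_equal(sb$n_loss, 9)
  empty <- summarize_region_table(a[0, ])
  expect_equal(unlist(empty), c(n_regions = 0, n_gain = 0, n_loss = 0,
                                total_gene_count = 0))
})

test_that("BED export converts to 0-based half-open coordinates", {
  a <- read_region_table(cgh_fixture("table1a.tsv"))[1, ]
  path <- tempfile(fileext = ".bed")
  bed <- write_regions_bed(a, path)
  expect_equal(bed$chromStart, a$start - 1)
  expect_equal(bed$chromEnd, a$end)
  expect_true(file.exists(path))
  unlink(path)
})
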