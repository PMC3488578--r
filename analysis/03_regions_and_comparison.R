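#!/usr/bin/env Rscript
# Step 3: cohort frequency tables, imbalance regions at the >= 50%
# threshold, cross-cohort common regions (strict > 50%), and
# subtype/stage differential-frequency tables for cohort A. Also
# reproduces the shipped fixture-table summaries as a cross-check of the
# same statistics on published-style inputs.
#
# Reads results/ of step 2; writes regions_<cohort>.tsv, common.tsv,
# strat_subtype_a.tsv, strat_stage_a.tsv and BED exports.

library(cghcohort)

design <- make_array_design(10, 40, 20, 3, seed = 101)

read_calls <- function(cohort) {
  df <- utils::read.delim(sprintf("results/calls_%s.tsv", cohort))
  samples <- setdiff(names(df), "clone_id")
  lapply(samples, function(s) {
    out <- design$clones[, c("clone_id", "chromosome", "start", "end")]
    out$state <- as.integer(df[[s]])
    structure(out, class = c("state_calls", "data.frame"))
  })
}

regions <- list()
for (cohort in c("a", "b")) {
  calls <- read_calls(cohort)
  freqs <- clone_frequencies(calls)
  reg <- call_imbalance_regions(freqs, threshold_pct = 50, min_clones = 2)
  regions[[cohort]] <- reg
  write_tsv_table(reg, sprintf("results/regions_%s.tsv", cohort))
  write_regions_bed(reg, sprintf("results/regions_%s.bed", cohort))
  s <- summarize_region_table(reg)
  cat(sprintf("cohort %s: %d imbalance regions (%d gain, %d loss)\n",
              toupper(cohort), s$n_regions, s$n_gain, s$n_loss))
}

common <- common_regions(regions$a, regions$b, strict_threshold_pct = 50)
write_tsv_table(common, "results/common.tsv")
cat(sprintf("common regions (strict > 50%% in both cohorts): %d (%d gain, %d loss)\n",
            nrow(common), sum(common$direction == "gain"),
            sum(common$direction == "loss")))

calls_a <- read_calls("a")
meta_a <- utils::read.delim("results/meta_a.tsv")
for (fac in c("subtype", "stage")) {
  ent <- stratified_differential_regions(calls_a, meta_a, fac,
                                         report_threshold_pct = 50)
  write_tsv_table(ent, sprintf("results/strat_%s_a.tsv", fac))
  cat(sprintf("cohort A %s comparison: %d region(s) with difference >= 50%%\n",
              fac, nrow(ent)))
  if (nrow(ent)) {
    print(ent[, c("chromosome", "a_direction", "a_freq_pct",
                  "b_direction", "b_freq_pct", "diff_pct")])
  }
}

# cross-check the same statistics on the shipped fixture tables
fa <- read_region_table(cgh_fixture("table1a.tsv"))
fb <- read_region_table(cgh_fixture("table1b.tsv"))
fc <- common_regions(fa, fb, 50)
cat(sprintf("fixture tables: %d + %d regions, %d + %d genes, %d common regions\n",
            nrow(fa), nrow(fb),
            summarize_region_table(fa)$total_gene_count,
            summarize_region_table(fb)$total_gene_count, nrow(fc)))
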