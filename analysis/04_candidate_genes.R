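#!/usr/bin/env Rscript
# Step 4: candidate-gene funnel on cohort A's called regions. A synthetic
# gene annotation is tiled over the array footprint; one gene set is
# enriched among altered-region genes (emulating a disease-pathway hit),
# the rest are random draws; expression ratios are simulated at 90%
# concordance with the planted copy-number direction.
#
# Reads results/ of steps 1 and 3; writes candidates.tsv, funnel.tsv,
# enrichment.tsv.

library(cghcohort)

design <- make_array_design(10, 40, 20, 3, seed = 101)
regions <- utils::read.delim("results/regions_a.tsv",
                             colClasses = c(chromosome = "character"))

# synthetic annotation: 15 genes tiled through each design region
set.seed(501)
genes <- do.call(rbind, lapply(split(design$clones, design$clones$region_label),
  function(cl) {
    n <- 15
    span <- max(cl$end) - min(cl$start)
    starts <- min(cl$start) + sort(sample.int(span - 20000, n))
    data.frame(symbol = sprintf("G_%s_%02d", cl$region_label[1], seq_len(n)),
               chromosome = cl$chromosome[1],
               start = starts, end = starts + 19999,
               stringsAsFactors = FALSE)
  }))
rownames(genes) <- NULL
genes$known_in_lung_cancer <- runif(nrow(genes)) < 0.4

# per-gene planted state: direction of the planted region it falls in
planted <- list(R01 = 1L, R03 = 1L, R05 = 1L, R07 = -1L, R09 = -1L, R10 = 1L)
region_of <- sub("^G_(R[0-9]+)_.*$", "\\1", genes$symbol)
gene_state <- setNames(vapply(region_of, function(r)
  if (is.null(planted[[r]])) 0L else planted[[r]], integer(1)), genes$symbol)

expression <- simulate_expression(gene_state, concordance_prob = 0.9,
                                  seed = 502)
expression <- expression[, c("symbol", "ratio")]

# gene sets: one concentrated in altered-region genes, four random
altered_syms <- names(gene_state)[gene_state != 0]
gene_sets <- rbind(
  data.frame(set = "pathway_hit",
             symbol = sample(altered_syms, min(40, length(altered_syms)))),
  do.call(rbind, lapply(1:4, function(k)
    data.frame(set = sprintf("random_%d", k),
               symbol = sample(genes$symbol, 30))))
)

res <- select_candidates(regions, genes, gene_sets, expression,
                         alpha = 0.05, freq_threshold_pct = 50)
write_tsv_table(res$candidates, "results/candidates.tsv")
write_tsv_table(res$funnel, "results/funnel.tsv")
write_tsv_table(res$enrichment, "results/enrichment.tsv")

cat("selection funnel (survivors per stage):\n")
print(res$funnel)
cat(sprintf("enriched sets at P < 0.05: %s\n",
            paste(res$enrichment$set[res$enrichment$p < 0.05], collapse = ", ")))
cat(sprintf("novel candidates: %d of %d\n",
            sum(res$candidates$novel), nrow(res$candidates)))
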