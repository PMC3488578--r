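#!/usr/bin/env Rscript
# Step 5: validation-assay scoring for one candidate locus (the planted
# 73%-prevalence gain region R03 of cohort A). Carrier samples are
# "amplified"; qPCR Ct pairs, CISH nucleus counts and IHC percentages are
# simulated with assay noise, then scored with the package's rules:
# delta-Ct ratios + Welch two-tailed t test, the > 40%-of->=-4-signals
# CISH rule, the > 50%-positive IHC rule, and chi-square association of
# overexpression with tumor stage.
#
# Reads results/ of step 1; writes validation_summary.tsv.

library(cghcohort)

truth <- utils::read.delim("results/truth_a.tsv")
meta <- utils::read.delim("results/meta_a.tsv")
design <- make_array_design(10, 40, 20, 3, seed = 101)
r03_clone <- design$clones$clone_id[design$clones$region_label == "R03"][1]
row <- truth[truth$clone_id == r03_clone, meta$sample_id]
amplified <- setNames(as.logical(row == 1), meta$sample_id)
cat(sprintf("R03 carriers: %d of %d samples\n", sum(amplified), length(amplified)))

v <- simulate_validation(amplified, dosage = 2, ct_noise_sd = 0.15,
                         n_nuclei = 120, ihc_sd = 8, seed = 601)

tum <- v$ct[v$ct$tissue == "tumor", ]
nor <- v$ct[v$ct$tissue == "normal", ]
rt <- relative_ratio(tum$ct_target, tum$ct_reference)
rn <- relative_ratio(nor$ct_target, nor$ct_reference)
qq <- group_mean_test(rt, rn)
cat(sprintf("qPCR: mean tumor ratio %.2f vs normal %.2f, t = %.2f, P = %.2g\n",
            qq$mean_tumor, qq$mean_normal, qq$t, qq$p))

cish <- cish_call(v$cish$n_nuclei_ge4, v$cish$n_nuclei_evaluated)
cat(sprintf("CISH: %d%% amplification-positive (truth: %d%% carriers)\n",
            positive_frequency(cish), positive_frequency(amplified)))

ihc <- ihc_call(v$ihc$percent_positive)
cat(sprintf("IHC: %d%% overexpression-positive\n", positive_frequency(ihc)))

tab <- table(factor(ihc, c(FALSE, TRUE)),
             factor(meta$stage, c("early", "late")))
cs <- chisq_association(as.matrix(tab))
cat(sprintf("overexpression vs stage: chi2 = %.2f, P = %.2g\n", cs$chi2, cs$p))

write_tsv_table(data.frame(
  measure = c("qpcr_mean_tumor", "qpcr_mean_normal", "qpcr_t", "qpcr_p",
              "cish_positive_pct", "ihc_positive_pct",
              "stage_chi2", "stage_p"),
  value = c(qq$mean_tumor, qq$mean_normal, qq$t, qq$p,
            positive_frequency(cish), positive_frequency(ihc),
            cs$chi2, cs$p)), "results/validation_summary.tsv")
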