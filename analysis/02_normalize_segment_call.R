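#!/usr/bin/env Rscript
# Step 2: hybridize each planted truth profile to a spot table (shared
# block shifts — a print-run property), estimate block statistics from a
# self-self array, normalize block-wise, aggregate triplicate spots,
# segment each profile with the exact Bayesian changepoint model and
# call ternary states at tau = 3 self-self SDs.
#
# Reads results/ of step 1; writes calls_<cohort>.tsv (clone x sample
# state matrix) and pipeline_params.tsv.

library(cghcohort)

design <- make_array_design(10, 40, 20, 3, seed = 101)  # as in step 1
shifts <- make_block_shifts(design, seed = 301)
noise_sd <- 0.2

selfself <- simulate_selfself(design, noise_sd = noise_sd,
                              block_shifts = shifts, seed = 302)

read_truth <- function(cohort) {
  tr <- utils::read.delim(sprintf("results/truth_%s.tsv", cohort))
  stopifnot(identical(tr$clone_id, design$clones$clone_id))
  samples <- setdiff(names(tr), "clone_id")
  lapply(samples, function(s) {
    structure(list(sample_id = s,
                   states = setNames(as.integer(tr[[s]]), tr$clone_id),
                   purity = 1),
              class = "truth_profile")
  })
}

for (cohort in c("a", "b")) {
  profiles <- read_truth(cohort)
  spots <- lapply(seq_along(profiles), function(k)
    simulate_hybridization(design, profiles[[k]], noise_sd = noise_sd,
                           block_shifts = shifts,
                           seed = 400 + 100 * (cohort == "b") + k))
  names(spots) <- vapply(profiles, `[[`, "", "sample_id")
  res <- cohort_state_calls(spots, selfself, design)
  states <- vapply(res$calls, function(x) x$state, integer(nrow(design$clones)))
  write_tsv_table(cbind(design$clones[, "clone_id", drop = FALSE], states),
                  sprintf("results/calls_%s.tsv", cohort))
  n_miss <- sum(is.na(states))
  cat(sprintf("cohort %s: tau = %.3f, %d samples called, %d missing clone calls\n",
              toupper(cohort), res$tau, ncol(states), n_miss))
  if (cohort == "a") {
    write_tsv_table(data.frame(param = c("noise_sd", "tau", "p_c"),
                               value = c(noise_sd, res$tau, 0.01)),
                    "results/pipeline_params.tsv")
  }
}
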