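# End-to-end composition: spot tables -> normalized clone profiles ->
# segmentation -> ternary calls, for a whole cohort.

#' Normalize, aggregate, segment and call one sample
#'
#' @param spots Raw spot table for one hybridization.
#' @param design The `array_design`.
#' @param stats `block_stats` from the cohort's self-self array.
#' @param tau Calling threshold (z units); see [default_tau()].
#' @param p_c Prior changepoint probability (default 0.01).
#' @param prior A [nig_prior()].
#' @param max_replicate_sd Replicate QC cutoff (default 1.0).
#' @param sample_id Optional label.
#' @return A `state_calls` data.frame.
#' @export
process_sample <- function(spots, design, stats, tau, p_c = 0.01,
                           prior = nig_prior(), max_replicate_sd = 1.0,
                           sample_id = NA_character_) {
  z <- normalize_blockwise(spots, stats)
  prof <- aggregate_replicates(z, design, max_replicate_sd,
                               sample_id = sample_id)
  seg <- segment_profile(prof, p_c = p_c, prior = prior)
  call_states(seg, tau)
}

#' Run the calling pipeline over a cohort of spot tables
#'
#' Estimates block statistics and the calling threshold once from the
#' cohort's self-self hybridization, then processes every tumor array
#' with them.
#'
#' @param spot_tables Named list of raw tumor spot tables.
#' @param selfself Raw self-self spot table.
#' @param design The `array_design`.
#' @param tau_multiplier SD multiplier for [default_tau()] (default 3).
#' @param p_c,prior,max_replicate_sd Passed to [process_sample()].
#' @return List: `calls` (list of `state_calls`), `stats`, `tau`.
#' @export
cohort_state_calls <- function(spot_tables, selfself, design,
                               tau_multiplier = 3, p_c = 0.01,
                               prior = nig_prior(), max_replicate_sd = 1.0) {
  stats <- block_stats_from_selfself(selfself, design)
  self_prof <- aggregate_replicates(normalize_blockwise(selfself, stats),
                                    design, max_replicate_sd)
  tau <- default_tau(self_prof, tau_multiplier)
  ids <- names(spot_tables)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(spot_tables))
  calls <- lapply(seq_along(spot_tables), function(k) {
    process_sample(spot_tables[[k]], design, stats, tau, p_c, prior,
                   max_replicate_sd, sample_id = ids[k])
  })
  names(calls) <- ids
  list(calls = calls, stats = stats, tau = tau)
}
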