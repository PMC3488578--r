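# Block-wise normalization: per-block mean/SD estimated from a self-self
# hybridization of the reference DNA, applied as a z-transform to tumor
# spot ratios, followed by replicate aggregation to one value per clone.

#' Estimate per-block statistics from a self-self hybridization
#'
#' The self-self array (reference DNA vs itself) has no biological signal,
#' so its per-block spot mean and SD estimate the print block's systematic
#' shift and noise scale. SD uses the n-1 denominator.
#'
#' @param selfself Spot table (spot_id, block, clone_id, log2ratio,
#'   qc_flag) from a self-self hybridization.
#' @param design An `array_design`; every design block must be represented
#'   by at least 2 unflagged spots.
#' @param min_sd Blocks with SD below this are rejected as degenerate
#'   (default 1e-6).
#' @return An object of class `block_stats`: data.frame(block, mean, sd).
#' @export
block_stats_from_selfself <- function(selfself, design, min_sd = 1e-6) {
  stopifnot(inherits(design, "array_design"))
  ok <- selfself$qc_flag == 0
  blocks <- seq_len(design$n_blocks)
  n_ok <- tabulate(selfself$block[ok], nbins = design$n_blocks)
  if (any(n_ok < 2)) {
    stop(sprintf("block(s) %s have fewer than 2 usable self-self spots",
                 paste(blocks[n_ok < 2], collapse = ", ")), call. = FALSE)
  }
  mu <- vapply(blocks, function(b) mean(selfself$log2ratio[ok & selfself$block == b]),
               numeric(1))
  sdev <- vapply(blocks, function(b) stats::sd(selfself$log2ratio[ok & selfself$block == b]),
                 numeric(1))
  if (any(sdev < min_sd)) {
    stop(sprintf("degenerate self-self block(s) with SD < %g: %s", min_sd,
                 paste(blocks[sdev < min_sd], collapse = ", ")), call. = FALSE)
  }
  structure(data.frame(block = blocks, mean = mu, sd = sdev),
            class = c("block_stats", "data.frame"))
}

#' Block-wise z-normalization of a spot table
#'
#' Standardizes each spot's log2 ratio by its block's self-self mean and
#' SD: z = (r - mu_b) / sigma_b. QC flags pass through unchanged. The
#' transform is affine within a block, so spot ordering within a block is
#' preserved.
#'
#' @param spots Spot table to normalize.
#' @param stats A `block_stats` object covering every block in `spots`.
#' @return The spot table with `log2ratio` replaced by its z-value.
#' @export
normalize_blockwise <- function(spots, stats) {
  idx <- match(spots$block, stats$block)
  if (anyNA(idx)) {
    stop(sprintf("no block statistics for block(s): %s",
                 paste(sort(unique(spots$block[is.na(idx)])), collapse = ", ")),
         call. = FALSE)
  }
  spots$log2ratio <- (spots$log2ratio - stats$mean[idx]) / stats$sd[idx]
  spots
}

#' Collapse replicate spots to one value per clone
#'
#' Summarizes the unflagged replicates of each clone by their median
#' (robust to one bad spot of a triplicate; `summary = "mean"` is
#' available). A clone is marked missing (NA) when fewer than 2 usable
#' replicates remain or when the replicate SD exceeds `max_replicate_sd`.
#'
#' @param normalized Normalized spot table.
#' @param design An `array_design` giving clone order and coordinates.
#' @param max_replicate_sd Replicate-SD QC cutoff on the z scale
#'   (default 1.0).
#' @param summary "median" (default) or "mean".
#' @param sample_id Optional sample label attached as an attribute.
#' @return A `clone_profile`: data.frame(clone_id, chromosome, start, end,
#'   value) in genome order, NA value marking a failed clone.
#' @export
aggregate_replicates <- function(normalized, design, max_replicate_sd = 1.0,
                                 summary = c("median", "mean"),
                                 sample_id = NA_character_) {
  stopifnot(inherits(design, "array_design"))
  summary <- match.arg(summary)
  fun <- if (summary == "median") stats::median else mean
  ok <- normalized$qc_flag == 0
  vals <- split(normalized$log2ratio[ok],
                factor(normalized$clone_id[ok], levels = design$clones$clone_id))
  value <- vapply(vals, function(v) {
    if (length(v) < 2) return(NA_real_)
    if (stats::sd(v) > max_replicate_sd) return(NA_real_)
    fun(v)
  }, numeric(1))
  out <- design$clones[, c("clone_id", "chromosome", "start", "end")]
  out$value <- unname(value[out$clone_id])
  structure(out, class = c("clone_profile", "data.frame"),
            sample_id = sample_id)
}
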