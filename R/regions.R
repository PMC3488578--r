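# Cohort-level frequency tables, imbalance-region calling at a frequency
# threshold, cross-cohort common regions, and the stratified
# signed-frequency difference statistic.

#' Per-clone gain/loss frequencies across a cohort
#'
#' For each clone, the fraction of samples called +1 (gain) and -1 (loss).
#' Clones missing in a sample are excluded from that clone's numerator and
#' denominator, so frequencies are over the samples actually observed at
#' the clone.
#'
#' @param calls List of `state_calls` sharing one design (same clones in
#'   the same order).
#' @return A `cohort_freq` data.frame: clone_id, chromosome, start, end,
#'   n_obs, f_gain, f_loss; attribute `n_samples`.
#' @export
clone_frequencies <- function(calls) {
  if (length(calls) == 0) stop("empty cohort", call. = FALSE)
  ids <- calls[[1]]$clone_id
  for (k in seq_along(calls)) {
    if (!identical(calls[[k]]$clone_id, ids)) {
      stop("all state calls must share one design (same clones, same order)",
           call. = FALSE)
    }
  }
  S <- vapply(calls, function(x) as.numeric(x$state), numeric(length(ids)))
  S <- matrix(S, nrow = length(ids))
  n_obs <- rowSums(!is.na(S))
  f_gain <- rowSums(S == 1, na.rm = TRUE) / pmax(n_obs, 1)
  f_loss <- rowSums(S == -1, na.rm = TRUE) / pmax(n_obs, 1)
  f_gain[n_obs == 0] <- NA_real_
  f_loss[n_obs == 0] <- NA_real_
  out <- calls[[1]][, c("clone_id", "chromosome", "start", "end")]
  out$n_obs <- n_obs
  out$f_gain <- f_gain
  out$f_loss <- f_loss
  structure(as.data.frame(out), class = c("cohort_freq", "data.frame"),
            n_samples = length(calls))
}

# empty region table with the canonical columns
.empty_regions <- function() {
  data.frame(chromosome = character(0), cytoband = character(0),
             start = numeric(0), end = numeric(0),
             direction = character(0), freq_pct = numeric(0),
             n_clones = integer(0), gene_n = integer(0),
             stringsAsFactors = FALSE)
}

#' Call chromosomal imbalance regions from cohort frequencies
#'
#' A maximal run of consecutive clones (genome order, one chromosome)
#' whose same-direction frequency reaches `threshold_pct` and whose length
#' reaches `min_clones` becomes one region: start/end from the first/last
#' clone, frequency = the run's median per-clone frequency rounded to
#' integer percent (half away from zero).
#'
#' @param freqs A `cohort_freq` table (genome-ordered).
#' @param threshold_pct Inclusion threshold in percent, in (0, 100]
#'   (default 50; the run rule is `>=`).
#' @param min_clones Minimum clones per region (default 2, suppressing
#'   single-clone artifacts).
#' @return A region table: chromosome, cytoband (NA here), start, end,
#'   direction ("gain"/"loss"), freq_pct, n_clones, gene_n (NA).
#' @export
call_imbalance_regions <- function(freqs, threshold_pct = 50, min_clones = 2) {
  if (!(threshold_pct > 0 && threshold_pct <= 100)) {
    stop("`threshold_pct` must lie in (0, 100]", call. = FALSE)
  }
  out <- list()
  for (dir in c("gain", "loss")) {
    f <- if (dir == "gain") freqs$f_gain else freqs$f_loss
    pct <- 100 * f
    hit <- !is.na(pct) & pct >= threshold_pct
    for (ch in unique(freqs$chromosome)) {
      rows <- which(freqs$chromosome == ch)
      r <- rle(hit[rows])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values & r$lengths >= min_clones)) {
        idx <- rows[starts[k]:ends[k]]
        out[[length(out) + 1]] <- data.frame(
          chromosome = ch, cytoband = NA_character_,
          start = freqs$start[idx[1]], end = freqs$end[idx[length(idx)]],
          direction = dir,
          freq_pct = round_half_away(stats::median(pct[idx])),
          n_clones = length(idx), gene_n = NA_integer_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(.empty_regions())
  res <- do.call(rbind, out)
  res <- res[order(match(res$chromosome, unique(freqs$chromosome)), res$start), ]
  rownames(res) <- NULL
  res
}

#' Region size in megabases
#'
#' (end - start) / 1e6, rounded to 2 decimals, matching how printed region
#' tables report size from 1-based inclusive coordinates.
#'
#' @param start Region start (bp), or a region data.frame with
#'   start/end columns (then `end` is ignored).
#' @param end Region end (bp).
#' @return Numeric vector of sizes in Mb.
#' @export
region_size_mb <- function(start, end = NULL) {
  if (is.data.frame(start)) {
    end <- start$end
    start <- start$start
  }
  round((end - start) / 1e6, 2)
}

.regions_to_gr <- function(regions, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels = unique(regions$chromosome)
  GenomicRanges::GRanges(
    seqnames = factor(regions$chromosome, levels = seqlevels),
    ranges = IRanges::IRanges(start = regions$start, end = regions$end)
  )
}

#' Common imbalance regions between two cohorts
#'
#' Keeps regions with frequency strictly above `strict_threshold_pct` in
#' each table, intersects intervals that share chromosome and direction,
#' and merges overlapping or book-ended intersections of the same
#' chromosome and direction into one common region (the intersection
#' envelope). The reported frequency of a common region is the smaller of
#' the two cohort frequencies (the frequency both cohorts attain);
#' cytoband labels of the contributing rows are concatenated.
#'
#' @param a,b Region tables (as from [call_imbalance_regions()] or a
#'   transcribed fixture).
#' @param strict_threshold_pct Strict lower bound on frequency percent
#'   (default 50; rows at exactly 50 are excluded).
#' @return A region table of common regions.
#' @export
common_regions <- function(a, b, strict_threshold_pct = 50) {
  out <- list()
  for (dir in c("gain", "loss")) {
    ra <- a[a$direction == dir & a$freq_pct > strict_threshold_pct, , drop = FALSE]
    rb <- b[b$direction == dir & b$freq_pct > strict_threshold_pct, , drop = FALSE]
    if (!nrow(ra) || !nrow(rb)) next
    lev <- unique(c(ra$chromosome, rb$chromosome))
    gra <- .regions_to_gr(ra, lev)
    grb <- .regions_to_gr(rb, lev)
    hits <- GenomicRanges::findOverlaps(gra, grb)
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    inter <- IRanges::pintersect(gra[qi], grb[si])
    pair_freq <- pmin(ra$freq_pct[qi], rb$freq_pct[si])
    pair_label <- paste(ra$cytoband[qi], rb$cytoband[si], sep = "/")
    merged <- GenomicRanges::reduce(inter, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(merged)$revmap
    out[[length(out) + 1]] <- data.frame(
      chromosome = as.character(GenomicRanges::seqnames(merged)),
      cytoband = vapply(revmap, function(ix)
        paste(unique(pair_label[ix]), collapse = ";"), character(1)),
      start = GenomicRanges::start(merged),
      end = GenomicRanges::end(merged),
      direction = dir,
      freq_pct = vapply(revmap, function(ix) max(pair_freq[ix]), numeric(1)),
      n_clones = NA_integer_, gene_n = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(.empty_regions())
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$start), ]
  rownames(res) <- NULL
  res
}

#' Signed-frequency difference between two group entries
#'
#' Encodes each group's (direction, frequency) as a signed frequency
#' s = +f for gain, -f for loss, 0 when the group shows no alteration,
#' and returns D = |s_a - s_b| in percent. This is the statistic behind
#' "difference in alteration frequency" columns: a region lost in 25% of
#' one group but gained in 40% of the other differs by 65.
#'
#' @param dir_a,dir_b Direction per group: "gain", "loss" or "none"
#'   (NA treated as "none"). Vectorized.
#' @param f_a,f_b Frequencies in percent, in [0, 100].
#' @return D in percent, in [0, 200].
#' @export
signed_frequency_difference <- function(dir_a, f_a, dir_b, f_b) {
  if (any(c(f_a, f_b) < 0 | c(f_a, f_b) > 100, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 100]", call. = FALSE)
  }
  if (!all(c(dir_a, dir_b) %in% c("gain", "loss", "none", NA))) {
    stop("direction must be 'gain', 'loss' or 'none'", call. = FALSE)
  }
  sgn <- function(d) ifelse(is.na(d) | d == "none", 0, ifelse(d == "gain", 1, -1))
  abs(sgn(dir_a) * f_a - sgn(dir_b) * f_b)
}

# per-clone dominant signed frequency (percent): +f_gain if gain dominates,
# else -f_loss
.signed_dominant <- function(freqs) {
  ifelse(freqs$f_gain >= freqs$f_loss, 100 * freqs$f_gain, -100 * freqs$f_loss)
}

#' Regions with differential alteration frequency between two groups
#'
#' Splits a cohort by a two-level factor (tumor subtype ADC/SCC or stage
#' early/late), computes each group's per-clone dominant signed frequency,
#' and reports maximal runs of consecutive clones whose per-clone
#' signed-frequency difference reaches `report_threshold_pct`. Within a
#' run, each group is summarized by the median of its signed per-clone
#' frequencies (rounded to integer percent): the sign gives the group's
#' direction, the magnitude its frequency, and D is recomputed from the
#' two summaries; runs whose summarized D falls below the threshold are
#' dropped.
#'
#' @param calls List of `state_calls` sharing one design.
#' @param meta data.frame with sample_id and the factor column; rows in
#'   the same order as `calls`.
#' @param factor_name "subtype" or "stage" (a column of `meta` with
#'   exactly two observed levels).
#' @param report_threshold_pct Minimum difference D in percent (default 50).
#' @param min_clones Minimum run length (default 2).
#' @return data.frame: chromosome, start, end, n_clones, group_a, group_b,
#'   a_direction, a_freq_pct, b_direction, b_freq_pct, diff_pct.
#' @export
stratified_differential_regions <- function(calls, meta,
                                            factor_name = c("subtype", "stage"),
                                            report_threshold_pct = 50,
                                            min_clones = 2) {
  factor_name <- match.arg(factor_name)
  if (length(calls) != nrow(meta)) {
    stop("`calls` and `meta` must describe the same samples", call. = FALSE)
  }
  fac <- meta[[factor_name]]
  levels <- sort(unique(fac))
  if (length(levels) != 2) {
    stop(sprintf("factor '%s' must have exactly 2 observed levels", factor_name),
         call. = FALSE)
  }
  ia <- which(fac == levels[1])
  ib <- which(fac == levels[2])
  if (!length(ia) || !length(ib)) {
    stop("each factor level needs at least one sample", call. = FALSE)
  }
  fa <- clone_frequencies(calls[ia])
  fb <- clone_frequencies(calls[ib])
  sa <- .signed_dominant(fa)
  sb <- .signed_dominant(fb)
  D <- abs(sa - sb)
  hit <- !is.na(D) & D >= report_threshold_pct
  out <- list()
  summarize <- function(s) {
    med <- round_half_away(stats::median(s))
    if (med > 0) c("gain", med) else if (med < 0) c("loss", -med) else c("none", 0)
  }
  for (ch in unique(fa$chromosome)) {
    rows <- which(fa$chromosome == ch)
    r <- rle(hit[rows])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_clones)) {
      idx <- rows[starts[k]:ends[k]]
      suma <- summarize(sa[idx])
      sumb <- summarize(sb[idx])
      d <- signed_frequency_difference(suma[1], as.numeric(suma[2]),
                                       sumb[1], as.numeric(sumb[2]))
      if (d < report_threshold_pct) next
      out[[length(out) + 1]] <- data.frame(
        chromosome = ch, start = fa$start[idx[1]], end = fa$end[idx[length(idx)]],
        n_clones = length(idx),
        group_a = levels[1], group_b = levels[2],
        a_direction = suma[1], a_freq_pct = as.numeric(suma[2]),
        b_direction = sumb[1], b_freq_pct = as.numeric(sumb[2]),
        diff_pct = d, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), n_clones = integer(0),
                      group_a = character(0), group_b = character(0),
                      a_direction = character(0), a_freq_pct = numeric(0),
                      b_direction = character(0), b_freq_pct = numeric(0),
                      diff_pct = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a region table
#'
#' @param regions A region table with a `gene_n` column (0 allowed).
#' @return List: n_regions, n_gain, n_loss, total_gene_count.
#' @export
summarize_region_table <- function(regions) {
  list(n_regions = nrow(regions),
       n_gain = sum(regions$direction == "gain"),
       n_loss = sum(regions$direction == "loss"),
       total_gene_count = if (nrow(regions)) sum(regions$gene_n) else 0L)
}

#' Write a region table as BED
#'
#' Converts the table's 1-based inclusive coordinates to BED's 0-based
#' half-open convention. Name column is "cytoband|direction|freq".
#'
#' @param regions A region table.
#' @param path Output file.
#' @return Invisibly, the BED data.frame written.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chromosome,
                    chromStart = regions$start - 1,
                    chromEnd = regions$end,
                    name = paste(regions$cytoband, regions$direction,
                                 regions$freq_pct, sep = "|"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
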