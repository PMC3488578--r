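# Candidate-gene selection funnel: region-to-gene mapping, hypergeometric
# gene-set enrichment, copy-number/expression concordance, novelty split.

#' Map genes into imbalance regions
#'
#' A gene belongs to a region iff its interval overlaps the region
#' interval by at least 1 bp (any-overlap rule); the gene inherits the
#' region's direction. Counts are invariant to gene-table row order.
#'
#' @param regions A region table (chromosome, start, end, direction, ...).
#' @param genes Gene table: symbol, chromosome, start, end (1-based
#'   inclusive), plus optional columns carried through.
#' @return List: `genes` (the overlapping gene rows with `region_index`
#'   and `direction` added, one row per gene-region pair) and `counts`
#'   (integer vector, genes per region).
#' @export
genes_in_regions <- function(regions, genes) {
  counts <- integer(nrow(regions))
  if (!nrow(regions) || !nrow(genes)) {
    return(list(genes = cbind(genes[0, , drop = FALSE],
                              region_index = integer(0),
                              direction = character(0)),
                counts = counts))
  }
  lev <- unique(c(regions$chromosome, genes$chromosome))
  grr <- .regions_to_gr(regions, lev)
  grg <- GenomicRanges::GRanges(factor(genes$chromosome, levels = lev),
                                IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(grg, grr)
  gi <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  tab <- tabulate(ri, nbins = nrow(regions))
  counts <- as.integer(tab)
  out <- genes[gi, , drop = FALSE]
  out$region_index <- ri
  out$direction <- regions$direction[ri]
  rownames(out) <- NULL
  list(genes = out, counts = counts)
}

#' Upper-tail hypergeometric enrichment P value
#'
#' P(X >= x) for X hypergeometric: the probability of drawing at least
#' `x` genes of a set of size `K` when drawing `n` genes without
#' replacement from a universe of `N`. The inclusive upper tail is the
#' standard over-representation convention.
#'
#' @param x Observed overlap count.
#' @param K Gene-set size within the universe.
#' @param n Query (drawn) set size.
#' @param N Universe size.
#' @return P value in [0, 1].
#' @export
hypergeometric_p <- function(x, K, n, N) {
  v <- c(x, K, n, N)
  if (any(v < 0) || any(v != round(v))) {
    stop("arguments must be non-negative integers", call. = FALSE)
  }
  if (K > N || n > N || x > min(K, n)) {
    stop("require 0 <= x <= min(K, n) <= N", call. = FALSE)
  }
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Keep genes whose expression direction matches their copy-number direction
#'
#' A gained gene is concordant when its tumor/normal expression ratio is
#' above 1, a lost gene when below 1. Genes without expression data are
#' dropped (their count is reported via a message and the `n_no_expression`
#' attribute).
#'
#' @param genes Gene table with a `direction` column ("gain"/"loss"),
#'   e.g. from [genes_in_regions()].
#' @param expression data.frame(symbol, ratio) of tumor/normal ratios.
#' @return The concordant subset of `genes`, with `ratio` added.
#' @export
concordance_filter <- function(genes, expression) {
  idx <- match(genes$symbol, expression$symbol)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    message(sprintf("concordance_filter: dropping %d gene(s) without expression data",
                    n_missing))
  }
  genes$ratio <- expression$ratio[idx]
  keep <- !is.na(genes$ratio) &
    ((genes$direction == "gain" & genes$ratio > 1) |
       (genes$direction == "loss" & genes$ratio < 1))
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_no_expression") <- n_missing
  out
}

#' Run the candidate-gene selection funnel
#'
#' Stages: (1) genes overlapping regions whose frequency reaches
#' `freq_threshold_pct`; (2) genes belonging to at least one gene set
#' enriched at `P < alpha` (hypergeometric upper tail; universe = all
#' genes in the supplied table); (3) genes whose expression direction is
#' concordant with their copy-number direction; (4) partition by the
#' caller-supplied novelty flag. Each stage's survivor set is a subset of
#' the previous one, and every stage count is recorded.
#'
#' @param regions Region table.
#' @param genes Gene table (symbol, chromosome, start, end); an optional
#'   logical `known_in_lung_cancer` column drives the novelty split.
#' @param gene_sets data.frame(set, symbol).
#' @param expression data.frame(symbol, ratio).
#' @param alpha Enrichment significance cutoff (default 0.05); `alpha >= 1`
#'   disables the set filter entirely (permissive limit).
#' @param freq_threshold_pct Region-frequency filter (default 50, `>=`).
#' @param adjust "none" (default, a raw cutoff) or "BH"
#'   (Benjamini-Hochberg).
#' @return List: `candidates` (final gene table with `novel` flag),
#'   `funnel` (data.frame stage/count), `enrichment` (per-set x, K, n, N,
#'   p).
#' @export
select_candidates <- function(regions, genes, gene_sets, expression,
                              alpha = 0.05, freq_threshold_pct = 50,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!nrow(genes)) stop("empty gene universe", call. = FALSE)
  N <- length(unique(genes$symbol))
  kept_regions <- regions[regions$freq_pct >= freq_threshold_pct, , drop = FALSE]
  stage1 <- genes_in_regions(kept_regions, genes)$genes
  stage1 <- stage1[!duplicated(stage1$symbol), , drop = FALSE]
  query <- unique(stage1$symbol)
  sets <- split(gene_sets$symbol, gene_sets$set)
  enrichment <- do.call(rbind, lapply(names(sets), function(s) {
    members <- intersect(unique(sets[[s]]), unique(genes$symbol))
    K <- length(members)
    x <- length(intersect(query, members))
    data.frame(set = s, x = x, K = K, n = length(query), N = N,
               p = if (K == 0) 1 else hypergeometric_p(x, K, length(query), N),
               stringsAsFactors = FALSE)
  }))
  if (is.null(enrichment)) {
    enrichment <- data.frame(set = character(0), x = integer(0), K = integer(0),
                             n = integer(0), N = integer(0), p = numeric(0))
  }
  p_use <- if (adjust == "BH") stats::p.adjust(enrichment$p, "BH") else enrichment$p
  if (alpha >= 1) {
    # permissive limit: no set is excluded, so the filter passes everything
    stage2 <- stage1
  } else {
    sig_sets <- enrichment$set[p_use < alpha]
    in_sig <- unique(gene_sets$symbol[gene_sets$set %in% sig_sets])
    stage2 <- stage1[stage1$symbol %in% in_sig, , drop = FALSE]
  }
  stage3 <- concordance_filter(stage2, expression)
  novel_flag <- if ("known_in_lung_cancer" %in% names(stage3)) {
    !stage3$known_in_lung_cancer
  } else rep(NA, nrow(stage3))
  stage3$novel <- novel_flag
  funnel <- data.frame(
    stage = c("region_genes", "enriched", "concordant", "novel"),
    count = c(nrow(stage1), nrow(stage2), nrow(stage3),
              sum(novel_flag, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  list(candidates = stage3, funnel = funnel, enrichment = enrichment)
}
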