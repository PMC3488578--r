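# Validation-assay scoring: relative qPCR ratios with two-tailed t tests,
# CISH amplification calls, IHC overexpression calls, and chi-square
# association with clinicopathological parameters.

#' Relative dosage/expression ratio from a Ct pair
#'
#' Delta-Ct quantification: ratio = efficiency^-(Ct_target -
#' Ct_reference). At perfect efficiency 2, one cycle earlier target
#' amplification means a doubled relative quantity.
#'
#' @param ct_target Target-gene threshold cycles (vectorized).
#' @param ct_reference Internal-control threshold cycles.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Relative ratio(s), > 0.
#' @export
relative_ratio <- function(ct_target, ct_reference, efficiency = 2) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  efficiency^(-(ct_target - ct_reference))
}

#' Two-tailed t test of tumor vs normal mean ratios
#'
#' Welch (unequal-variance) two-sample t test by default; `paired = TRUE`
#' treats the vectors as matched tumor/normal pairs (in order).
#'
#' @param tumor_ratios,normal_ratios Numeric vectors (each >= 2 values).
#' @param paired Paired test (default FALSE).
#' @return List: mean_tumor, mean_normal, t, p (two-sided).
#' @export
group_mean_test <- function(tumor_ratios, normal_ratios, paired = FALSE) {
  if (length(tumor_ratios) < 2 || length(normal_ratios) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  tt <- stats::t.test(tumor_ratios, normal_ratios, paired = paired,
                      var.equal = FALSE)
  list(mean_tumor = mean(tumor_ratios), mean_normal = mean(normal_ratios),
       t = unname(tt$statistic), p = tt$p.value)
}

#' CISH amplification call
#'
#' Amplification-positive iff strictly more than 40% of the evaluated
#' nuclei show >= 4 probe signals; requires at least 100 intact,
#' non-overlapping nuclei.
#'
#' @param n_nuclei_ge4 Nuclei with >= 4 signals (vectorized).
#' @param n_nuclei_evaluated Nuclei evaluated (each >= 100).
#' @param min_nuclei QC minimum (default 100).
#' @param frac_threshold Call threshold as a fraction (default 0.40,
#'   strict `>`).
#' @return Logical vector of amplification calls.
#' @export
cish_call <- function(n_nuclei_ge4, n_nuclei_evaluated, min_nuclei = 100,
                      frac_threshold = 0.40) {
  if (any(n_nuclei_ge4 < 0 | n_nuclei_ge4 > n_nuclei_evaluated)) {
    stop("require 0 <= n_nuclei_ge4 <= n_nuclei_evaluated", call. = FALSE)
  }
  if (any(n_nuclei_evaluated < min_nuclei)) {
    stop(sprintf("fewer than %d nuclei evaluated", min_nuclei), call. = FALSE)
  }
  n_nuclei_ge4 / n_nuclei_evaluated > frac_threshold
}

#' IHC overexpression call
#'
#' High expression iff strictly more than `pct_threshold` percent of tumor
#' cells stain positive (graded against internal normal-cell controls).
#'
#' @param percent_positive Percent of positive tumor cells, in [0, 100]
#'   (vectorized).
#' @param pct_threshold Threshold percent (default 50, strict `>`).
#' @return Logical vector of overexpression calls.
#' @export
ihc_call <- function(percent_positive, pct_threshold = 50) {
  if (any(percent_positive < 0 | percent_positive > 100)) {
    stop("`percent_positive` must lie in [0, 100]", call. = FALSE)
  }
  percent_positive > pct_threshold
}

#' Positive-call frequency in whole percent
#'
#' @param calls Logical vector (non-empty).
#' @return round(100 * positives / total), half away from zero.
#' @export
positive_frequency <- function(calls) {
  if (!length(calls)) stop("empty call list", call. = FALSE)
  round_half_away(100 * mean(calls))
}

#' Chi-square association for a 2x2 table
#'
#' Pearson chi-square without continuity correction (Yates available via
#' `correct = TRUE`), df = 1, two-sided P. Used to relate overexpression
#' calls to clinicopathological parameters (sex, age group, tumor type,
#' stage, smoking).
#'
#' @param table 2x2 matrix of non-negative integer counts with no zero
#'   row or column margin.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List: chi2, p.
#' @export
chisq_association <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(chi2 = unname(ct$statistic), p = ct$p.value)
}
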