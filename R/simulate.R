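# Synthetic-data generators: array designs, planted copy-number truth,
# hybridizations, expression ratios and validation-assay measurements.
# Everything is seed-deterministic so downstream stages can be tested
# against known ground truth without any external download.

#' Build a synthetic BAC-array design
#'
#' Creates a non-gapped tiling of BAC clones over `n_regions` synthetic
#' chromosome regions, mimicking a targeted array in which every clone is
#' spotted in `replicates` copies and assigned to one of `n_blocks` print
#' blocks (round-robin, so block membership is uncorrelated with genome
#' position). Regions are placed on a recycling set of chromosomes with
#' large gaps between regions that share a chromosome.
#'
#' @param n_regions Number of contiguous target regions (>= 1).
#' @param clones_per_region Clones tiled per region (>= 1).
#' @param n_blocks Number of print blocks (>= 1).
#' @param replicates Spots per clone (>= 1); 3 emulates triplicate spotting.
#' @param seed Integer seed; the design is deterministic given it.
#' @param clone_length Tiled clone length in bp (default 150000, a typical
#'   BAC insert).
#' @return An object of class `array_design`: a list with `clones` (a
#'   data.frame with clone_id, chromosome, start, end, cytoband,
#'   region_label, block; genome-ordered), `n_blocks`, `replicates`.
#' @export
make_array_design <- function(n_regions, clones_per_region, n_blocks,
                              replicates, seed = 1L,
                              clone_length = 150000L) {
  counts <- c(n_regions, clones_per_region, n_blocks, replicates)
  if (any(!is.finite(counts)) || any(counts < 1)) {
    stop("all design counts must be positive integers", call. = FALSE)
  }
  chrom_pool <- c("2", "3", "4", "6", "9", "10", "12", "13", "17", "X")
  with_seed(seed, {
    region_chrom <- chrom_pool[((seq_len(n_regions) - 1L) %% length(chrom_pool)) + 1L]
    # regions sharing a chromosome get successive, well-separated offsets
    occurrence <- stats::ave(seq_len(n_regions), region_chrom, FUN = seq_along)
    region_start <- 10e6 + (occurrence - 1L) * 60e6
    clones <- do.call(rbind, lapply(seq_len(n_regions), function(r) {
      starts <- region_start[r] + (seq_len(clones_per_region) - 1L) * clone_length
      data.frame(
        clone_id = sprintf("RP11-%02d-%04d", r, seq_len(clones_per_region)),
        chromosome = region_chrom[r],
        start = starts,
        end = starts + clone_length - 1L,
        cytoband = sprintf("%sq%02d", region_chrom[r], occurrence[r]),
        region_label = sprintf("R%02d", r),
        stringsAsFactors = FALSE
      )
    }))
    ord <- order(match(clones$chromosome, chrom_pool), clones$start)
    clones <- clones[ord, , drop = FALSE]
    rownames(clones) <- NULL
    clones$block <- ((seq_len(nrow(clones)) - 1L) %% n_blocks) + 1L
    structure(
      list(clones = clones, n_blocks = as.integer(n_blocks),
           replicates = as.integer(replicates)),
      class = "array_design"
    )
  })
}

#' @export
print.array_design <- function(x, ...) {
  cat(sprintf("<array_design> %d clones, %d regions, %d blocks, %d replicates/clone\n",
              nrow(x$clones), length(unique(x$clones$region_label)),
              x$n_blocks, x$replicates))
  invisible(x)
}

#' Specify a simulated cohort
#'
#' @param n_samples Cohort size.
#' @param regions Named list: `region_label = list(direction, prevalence)`,
#'   with optional `by = c(levelA = p, levelB = p)` giving the prevalence
#'   separately per subtype or stage level (the names select the factor
#'   levels). Direction is "gain" or "loss".
#' @param subtype_props Named proportions for ADC/SCC (must sum to 1).
#' @param stage_props Named proportions for early/late (must sum to 1).
#' @param purity Tumor cell fraction in (0, 1], attenuating ratio shifts.
#' @param seed Integer seed for carrier and label assignment.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples,
                        regions = list(),
                        subtype_props = c(ADC = 0.5, SCC = 0.5),
                        stage_props = c(early = 0.5, late = 0.5),
                        purity = 1,
                        seed = 1L) {
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (!r$direction %in% c("gain", "loss")) {
      stop(sprintf("region '%s': direction must be 'gain' or 'loss'", nm),
           call. = FALSE)
    }
    p <- if (is.null(r$by)) r$prevalence else unname(r$by)
    if (any(p < 0 | p > 1)) {
      stop(sprintf("region '%s': prevalence outside [0,1]", nm), call. = FALSE)
    }
  }
  if (abs(sum(subtype_props) - 1) > 1e-8 || abs(sum(stage_props) - 1) > 1e-8) {
    stop("factor proportions must sum to 1", call. = FALSE)
  }
  stop_if_not_scalar_prob(purity, "purity", open_left = TRUE)
  structure(list(n_samples = as.integer(n_samples), regions = regions,
                 subtype_props = subtype_props, stage_props = stage_props,
                 purity = purity, seed = as.integer(seed)),
            class = "cohort_spec")
}

# split n into counts proportional to props (largest-remainder)
.apportion <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Plant ternary copy-number truth across a cohort
#'
#' For every region in the cohort spec, exactly `round(prevalence * n)`
#' samples (drawn without replacement) carry the stated direction across
#' every clone of the region; all other clones are neutral (state 0).
#' Realizing prevalence as an exact rounded count rather than a Binomial
#' draw pins the cohort alteration fraction to the specification, which is
#' what a planted-truth generator should guarantee. When a region's
#' prevalence is given per factor level (`by`), carriers are drawn level
#' by level with the same exact-count rule.
#'
#' @param design An `array_design`.
#' @param spec A `cohort_spec`; all its region labels must exist in the design.
#' @return A list with `profiles` (list of `truth_profile`: sample_id,
#'   states named by clone_id, purity) and `meta` (data.frame sample_id,
#'   subtype, stage).
#' @export
simulate_truth <- function(design, spec) {
  stopifnot(inherits(design, "array_design"), inherits(spec, "cohort_spec"))
  known <- unique(design$clones$region_label)
  bad <- setdiff(names(spec$regions), known)
  if (length(bad)) {
    stop(sprintf("unknown region label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  n <- spec$n_samples
  with_seed(spec$seed, {
    sample_id <- sprintf("S%03d", seq_len(n))
    subtype <- sample(rep(names(spec$subtype_props),
                          .apportion(n, spec$subtype_props)))
    stage <- sample(rep(names(spec$stage_props),
                        .apportion(n, spec$stage_props)))
    meta <- data.frame(sample_id = sample_id, subtype = subtype,
                       stage = stage, stringsAsFactors = FALSE)
    states <- matrix(0L, nrow = nrow(design$clones), ncol = n,
                     dimnames = list(design$clones$clone_id, sample_id))
    for (nm in names(spec$regions)) {
      r <- spec$regions[[nm]]
      rows <- which(design$clones$region_label == nm)
      s <- if (r$direction == "gain") 1L else -1L
      if (is.null(r$by)) {
        k <- round_half_away(r$prevalence * n)
        carriers <- if (k > 0) sample(n, k) else integer(0)
      } else {
        fac <- if (all(names(r$by) %in% names(spec$subtype_props))) subtype else stage
        carriers <- unlist(lapply(names(r$by), function(lv) {
          idx <- which(fac == lv)
          k <- round_half_away(r$by[[lv]] * length(idx))
          if (k > 0) sample(idx, k) else integer(0)
        }), use.names = FALSE)
      }
      states[rows, carriers] <- s
    }
    profiles <- lapply(seq_len(n), function(j) {
      structure(list(sample_id = sample_id[j], states = states[, j],
                     purity = spec$purity),
                class = "truth_profile")
    })
    list(profiles = profiles, meta = meta)
  })
}

# expected log2 ratio for a ternary state at tumor purity p:
# copy number c = 2 + state vs diploid 2, mixed with (1-p) normal cells
state_shift <- function(state, purity = 1) {
  log2(1 + purity * state / 2)
}

#' Draw systematic per-block shifts for a design
#'
#' Block means are drawn once from Normal(0, `mean_sd`) and block noise
#' multipliers from Uniform over `mult_range`; the same shifts apply to
#' every hybridization of the design (a print-run effect), which is what
#' makes self-self-based block statistics transferable to tumor arrays.
#'
#' @param design An `array_design`.
#' @param mean_sd SD of block mean shifts (log2 units; default 0.1).
#' @param mult_range Range of block noise-SD multipliers (default 0.8-1.2).
#' @param seed Integer seed.
#' @return data.frame(block, mean, sd_mult), one row per block.
#' @export
make_block_shifts <- function(design, mean_sd = 0.1,
                              mult_range = c(0.8, 1.2), seed = 1L) {
  stopifnot(inherits(design, "array_design"))
  if (any(mult_range <= 0)) stop("block sd multipliers must be > 0", call. = FALSE)
  with_seed(seed, data.frame(
    block = seq_len(design$n_blocks),
    mean = stats::rnorm(design$n_blocks, 0, mean_sd),
    sd_mult = stats::runif(design$n_blocks, mult_range[1], mult_range[2])
  ))
}

#' Zero block shifts (no spatial artifact)
#' @param design An `array_design`.
#' @return data.frame(block, mean = 0, sd_mult = 1).
#' @export
zero_block_shifts <- function(design) {
  data.frame(block = seq_len(design$n_blocks), mean = 0, sd_mult = 1)
}

#' Simulate one hybridization to a spot table
#'
#' Each spot's log2 ratio is the purity-attenuated state shift of its clone
#' (+1 means 3 copies vs 2, i.e. log2(3/2); -1 means 1 copy vs 2) plus the
#' block mean shift plus Gaussian noise with SD `noise_sd * sd_mult[block]`.
#' A self-self reference hybridization is the same operation under an
#' all-zero truth (see [simulate_selfself()]).
#'
#' @param design An `array_design`.
#' @param truth A `truth_profile` whose states cover the design clones.
#' @param noise_sd Spot-level noise SD in log2 units (>= 0).
#' @param block_shifts data.frame(block, mean, sd_mult); see
#'   [make_block_shifts()].
#' @param seed Integer seed.
#' @param flag_prob Probability a spot is QC-flagged (default 0).
#' @return data.frame(spot_id, block, clone_id, log2ratio, qc_flag).
#' @export
simulate_hybridization <- function(design, truth, noise_sd = 0.2,
                                   block_shifts = zero_block_shifts(design),
                                   seed = 1L, flag_prob = 0) {
  stopifnot(inherits(design, "array_design"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (any(block_shifts$sd_mult <= 0)) stop("block sd multipliers must be > 0",
                                           call. = FALSE)
  if (!setequal(names(truth$states), design$clones$clone_id)) {
    stop("truth profile does not match the design's clones", call. = FALSE)
  }
  st <- truth$states[design$clones$clone_id]
  reps <- design$replicates
  clone_idx <- rep(seq_len(nrow(design$clones)), each = reps)
  block <- design$clones$block[clone_idx]
  bmean <- block_shifts$mean[match(block, block_shifts$block)]
  bmult <- block_shifts$sd_mult[match(block, block_shifts$block)]
  signal <- state_shift(st[clone_idx], truth$purity)
  with_seed(seed, {
    noise <- stats::rnorm(length(clone_idx), 0, noise_sd * bmult)
    qc <- if (flag_prob > 0) {
      as.integer(stats::runif(length(clone_idx)) < flag_prob)
    } else rep(0L, length(clone_idx))
    data.frame(
      spot_id = sprintf("%s.r%d", design$clones$clone_id[clone_idx],
                        rep(seq_len(reps), times = nrow(design$clones))),
      block = block,
      clone_id = design$clones$clone_id[clone_idx],
      log2ratio = signal + bmean + noise,
      qc_flag = qc,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a self-self reference hybridization
#'
#' Reference DNA against itself: all planted states zero, so spot ratios
#' contain only block shifts and noise. Used to estimate per-block
#' normalization statistics.
#'
#' @inheritParams simulate_hybridization
#' @return A spot table (see [simulate_hybridization()]).
#' @export
simulate_selfself <- function(design, noise_sd = 0.2,
                              block_shifts = zero_block_shifts(design),
                              seed = 1L, flag_prob = 0) {
  truth <- structure(
    list(sample_id = "selfself",
         states = stats::setNames(rep(0L, nrow(design$clones)),
                                  design$clones$clone_id),
         purity = 1),
    class = "truth_profile"
  )
  simulate_hybridization(design, truth, noise_sd, block_shifts, seed, flag_prob)
}

#' Simulate tumor/normal expression ratios concordant with copy number
#'
#' With probability `concordance_prob` a gene in a gained region gets an
#' expression ratio > 1 and a lost gene a ratio < 1; otherwise the
#' direction flips. `concordance_prob` is therefore the total probability
#' of a direction match (1 = perfectly concordant, 0.5 = expression
#' uninformative, 0 = perfectly anti-concordant). Neutral genes get a
#' ratio centered on 1.
#'
#' @param states Named integer vector of per-gene ternary states
#'   (+1 gain, 0 neutral, -1 loss), names = gene symbols.
#' @param concordance_prob Probability in [0,1] that an altered gene's
#'   expression direction follows its copy-number direction.
#' @param effect Fold-change magnitude for altered genes (default 2).
#' @param noise_sd SD of log2 jitter added to the magnitude (default 0.25).
#' @param seed Integer seed.
#' @return data.frame(symbol, state, ratio) of tumor/normal ratios.
#' @export
simulate_expression <- function(states, concordance_prob, effect = 2,
                                noise_sd = 0.25, seed = 1L) {
  stop_if_not_scalar_prob(concordance_prob, "concordance_prob")
  n <- length(states)
  with_seed(seed, {
    mag <- log2(effect) + abs(stats::rnorm(n, 0, noise_sd))
    concordant <- stats::runif(n) < concordance_prob
    dir <- ifelse(concordant, states, -states)
    l2 <- ifelse(states == 0, stats::rnorm(n, 0, noise_sd), dir * mag)
    data.frame(symbol = names(states), state = as.integer(states),
               ratio = 2^l2, stringsAsFactors = FALSE)
  })
}

#' Simulate validation-assay measurements for a marker gene
#'
#' Emulates the three orthogonal assays used to confirm array calls:
#' qPCR threshold cycles (amplified tumors shift the target Ct down by
#' log2(dosage) relative to the reference gene), CISH nucleus signal
#' counts (amplified tumors have a higher fraction of nuclei with >= 4
#' signals), and IHC percent-positive staining.
#'
#' @param amplified Named logical vector: per-sample amplification truth.
#' @param dosage Relative DNA dosage in amplified tumors (default 2).
#' @param ct_base Mean reference-gene Ct (default 26).
#' @param ct_noise_sd Ct measurement noise SD in cycles (default 0; set > 0
#'   for noisy assays).
#' @param n_nuclei Nuclei evaluated per CISH sample (default 100).
#' @param cish_frac Length-2 numeric: baseline and amplified probabilities
#'   that a nucleus shows >= 4 signals (default c(0.10, 0.60)).
#' @param ihc_mean Length-2 numeric: mean percent-positive for
#'   normal-expression and overexpressing samples (default c(25, 75)).
#' @param ihc_sd SD of percent-positive (default 0; truncated to [0,100]).
#' @param seed Integer seed.
#' @return List of data.frames: `ct` (sample_id, tissue, ct_target,
#'   ct_reference), `cish` (sample_id, n_nuclei_evaluated, n_nuclei_ge4),
#'   `ihc` (sample_id, percent_positive).
#' @export
simulate_validation <- function(amplified, dosage = 2, ct_base = 26,
                                ct_noise_sd = 0, n_nuclei = 100,
                                cish_frac = c(0.10, 0.60),
                                ihc_mean = c(25, 75), ihc_sd = 0,
                                seed = 1L) {
  stopifnot(is.logical(amplified), length(amplified) >= 1)
  ids <- names(amplified)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(amplified))
  n <- length(amplified)
  with_seed(seed, {
    ct_ref_t <- ct_base + stats::rnorm(n, 0, ct_noise_sd)
    ct_ref_n <- ct_base + stats::rnorm(n, 0, ct_noise_sd)
    ct <- rbind(
      data.frame(sample_id = ids, tissue = "tumor",
                 ct_target = ct_ref_t - ifelse(amplified, log2(dosage), 0) +
                   stats::rnorm(n, 0, ct_noise_sd),
                 ct_reference = ct_ref_t, stringsAsFactors = FALSE),
      data.frame(sample_id = ids, tissue = "normal",
                 ct_target = ct_ref_n + stats::rnorm(n, 0, ct_noise_sd),
                 ct_reference = ct_ref_n, stringsAsFactors = FALSE)
    )
    p4 <- ifelse(amplified, cish_frac[2], cish_frac[1])
    cish <- data.frame(
      sample_id = ids,
      n_nuclei_evaluated = rep(as.integer(n_nuclei), n),
      n_nuclei_ge4 = if (ihc_sd > 0 || ct_noise_sd > 0) {
        stats::rbinom(n, n_nuclei, p4)
      } else as.integer(round_half_away(n_nuclei * p4)),
      stringsAsFactors = FALSE
    )
    ihc <- data.frame(
      sample_id = ids,
      percent_positive = pmin(100, pmax(0,
        ifelse(amplified, ihc_mean[2], ihc_mean[1]) +
          stats::rnorm(n, 0, ihc_sd))),
      stringsAsFactors = FALSE
    )
    list(ct = ct, cish = cish, ihc = ihc)
  })
}
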