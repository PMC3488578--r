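# Bayesian changepoint segmentation of a genome-ordered clone profile.
#
# Model (per chromosome, over the observed clones): the sequence of
# normalized values is partitioned into contiguous segments; each of the
# n-1 between-clone gaps is independently a changepoint with prior
# probability p_c (equivalently, geometric segment lengths); each
# segment's level and variance carry a conjugate Normal-Inverse-Gamma
# prior, so the segment marginal likelihood is closed-form and the exact
# posterior over all 2^(n-1) partitions factorizes. A forward-backward
# dynamic program computes, in O(n^2), the exact posterior mean per clone,
# the posterior probability of a changepoint at every gap, and the model
# evidence. Gaps with posterior changepoint probability strictly above
# 0.5 are reported as breakpoints (ties therefore fall toward fewer
# breakpoints), and calling is done on the reported segments' posterior
# means.

#' Normal-Inverse-Gamma segment prior
#'
#' Conjugate prior on a segment's (mean, variance): mean ~ Normal(m0,
#' sigma^2/k0), variance ~ Inverse-Gamma(a0, b0). Small `k0` makes the
#' mean prior nearly flat; (a0, b0) set the observation-variance prior.
#'
#' @param m0 Prior segment mean (default 0, the normalized neutral level).
#' @param k0 Prior mean precision scale (> 0; default 0.01).
#' @param a0,b0 Inverse-Gamma shape and scale (> 0; defaults 1, 1).
#' @return A `nig_prior` list.
#' @export
nig_prior <- function(m0 = 0, k0 = 0.01, a0 = 1, b0 = 1) {
  if (k0 <= 0 || a0 <= 0 || b0 <= 0) {
    stop("k0, a0 and b0 must be positive", call. = FALSE)
  }
  structure(list(m0 = m0, k0 = k0, a0 = a0, b0 = b0), class = "nig_prior")
}

# Marginal likelihood (log) of y[i..j] for all j >= i at once, plus the
# NIG posterior segment mean, from prefix sums.
.seg_row <- function(i, n, cs, cs2, prior) {
  j <- i:n
  l <- j - i + 1
  S <- cs[j + 1] - cs[i]
  Q <- cs2[j + 1] - cs2[i]
  ybar <- S / l
  ss <- pmax(Q - S^2 / l, 0)
  kl <- prior$k0 + l
  al <- prior$a0 + l / 2
  bl <- prior$b0 + 0.5 * ss + prior$k0 * l * (ybar - prior$m0)^2 / (2 * kl)
  logml <- -l / 2 * log(2 * pi) + 0.5 * (log(prior$k0) - log(kl)) +
    lgamma(al) - lgamma(prior$a0) + prior$a0 * log(prior$b0) - al * log(bl)
  list(logml = logml, mean = (prior$k0 * prior$m0 + S) / kl)
}

# Exact posterior for one chromosome's observed values.
# Returns per-position posterior mean, per-gap changepoint probability,
# reported segment ids (from cp_prob > cp_threshold), per-position
# segment mean, and the log evidence.
.segment_chrom <- function(y, p_c, prior, cp_threshold = 0.5) {
  n <- length(y)
  lpc <- log(p_c)
  l1p <- log1p(-p_c)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  M <- matrix(-Inf, n, n)        # M[i, j] = log ML of segment y[i..j]
  Mm <- matrix(NA_real_, n, n)   # NIG posterior mean of that segment
  for (i in seq_len(n)) {
    r <- .seg_row(i, n, cs, cs2, prior)
    M[i, i:n] <- r$logml
    Mm[i, i:n] <- r$mean
  }
  cvec <- c(0, rep(lpc, n - 1))  # changepoint factor for a segment starting at i
  logF <- c(0, rep(-Inf, n))     # logF[j+1] = log weight of y[1..j]
  for (j in seq_len(n)) {
    i <- 1:j
    logF[j + 1] <- logsumexp(logF[i] + cvec[i] + M[i, j] + (j - i) * l1p)
  }
  logB <- c(rep(-Inf, n), 0)     # logB[i] = log weight of y[i..n], no leading cp factor
  for (i in rev(seq_len(n))) {
    j <- i:n
    tail_term <- ifelse(j < n, lpc + logB[j + 1], 0)
    logB[i] <- logsumexp(M[i, j] + (j - i) * l1p + tail_term)
  }
  logZ <- logF[n + 1]
  post_mean <- numeric(n)
  mass <- numeric(n)
  cp_prob <- numeric(max(n - 1, 0))
  for (i in seq_len(n)) {
    j <- i:n
    tail_term <- ifelse(j < n, lpc + logB[j + 1], 0)
    logp <- logF[i] + cvec[i] + M[i, j] + (j - i) * l1p + tail_term - logZ
    p <- exp(logp)
    if (n > 1 && i <= n - 1) {
      ends <- j[j <= n - 1]
      cp_prob[ends] <- cp_prob[ends] + p[seq_along(ends)]
    }
    # suffix sums assign each position t in i..n the mass of segments
    # [i, j] with j >= t
    pm_suffix <- rev(cumsum(rev(p * Mm[i, j])))
    p_suffix <- rev(cumsum(rev(p)))
    post_mean[j] <- post_mean[j] + pm_suffix
    mass[j] <- mass[j] + p_suffix
  }
  post_mean <- post_mean / mass  # mass == 1 up to numerical error
  breaks <- which(cp_prob > cp_threshold)
  seg_id <- cumsum(c(1L, as.integer(seq_len(n - 1) %in% breaks)))
  seg_mean <- numeric(n)
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    S <- sum(y[idx])
    seg_mean[idx] <- (prior$k0 * prior$m0 + S) / (prior$k0 + length(idx))
  }
  list(post_mean = post_mean, cp_prob = cp_prob, seg_id = seg_id,
       seg_mean = seg_mean, log_evidence = logZ)
}

#' Segment a clone profile by exact Bayesian changepoint analysis
#'
#' Computes, chromosome by chromosome over the non-missing clones, the
#' exact posterior of the piecewise-constant Gaussian product-partition
#' model described in the package vignette: geometric changepoint prior
#' with per-gap probability `p_c`, conjugate Normal-Inverse-Gamma segment
#' prior. Missing clones are skipped, never interpolated. Breakpoints are
#' the gaps whose posterior changepoint probability exceeds 0.5.
#'
#' @param profile A `clone_profile` (or data.frame with clone_id,
#'   chromosome, start, end, value), genome-ordered; NA values mark
#'   missing clones. Every chromosome must have at least one observed
#'   clone.
#' @param p_c Prior changepoint probability per between-clone gap,
#'   in (0, 1) (default 0.01).
#' @param prior A [nig_prior()].
#' @param cp_threshold Posterior probability above which a gap is reported
#'   as a breakpoint (default 0.5).
#' @return An object of class `segmentation`: list with `clones` (the
#'   input table plus posterior_mean, cp_prob_after [P(changepoint in the
#'   gap following this clone)], segment [chromosome-scoped id], and
#'   segment_mean; all NA for missing clones), `breakpoints`
#'   (data.frame chromosome, after_clone_id), `log_evidence` (named per
#'   chromosome), and the model settings.
#' @export
segment_profile <- function(profile, p_c = 0.01, prior = nig_prior(),
                            cp_threshold = 0.5) {
  if (!(is.numeric(p_c) && length(p_c) == 1 && p_c > 0 && p_c < 1)) {
    stop("`p_c` must lie strictly between 0 and 1", call. = FALSE)
  }
  stopifnot(inherits(prior, "nig_prior"))
  df <- as.data.frame(profile)
  df$posterior_mean <- NA_real_
  df$cp_prob_after <- NA_real_
  df$segment <- NA_character_
  df$segment_mean <- NA_real_
  chroms <- unique(df$chromosome)
  ev <- stats::setNames(numeric(length(chroms)), chroms)
  bp <- list()
  for (ch in chroms) {
    rows <- which(df$chromosome == ch)
    obs <- rows[!is.na(df$value[rows])]
    if (length(obs) == 0) {
      stop(sprintf("chromosome %s has no observed clones", ch), call. = FALSE)
    }
    res <- .segment_chrom(df$value[obs], p_c, prior, cp_threshold)
    df$posterior_mean[obs] <- res$post_mean
    if (length(obs) > 1) {
      df$cp_prob_after[obs[-length(obs)]] <- res$cp_prob
    }
    df$segment[obs] <- sprintf("%s.%d", ch, res$seg_id)
    df$segment_mean[obs] <- res$seg_mean
    ev[ch] <- res$log_evidence
    brk <- which(res$cp_prob > cp_threshold)
    if (length(brk)) {
      bp[[ch]] <- data.frame(chromosome = ch,
                             after_clone_id = df$clone_id[obs[brk]],
                             stringsAsFactors = FALSE)
    }
  }
  breakpoints <- if (length(bp)) do.call(rbind, bp) else
    data.frame(chromosome = character(0), after_clone_id = character(0))
  rownames(breakpoints) <- NULL
  structure(list(clones = df, breakpoints = breakpoints, log_evidence = ev,
                 p_c = p_c, prior = prior, cp_threshold = cp_threshold),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d clones (%d observed), %d breakpoints, p_c = %g\n",
              nrow(x$clones), sum(!is.na(x$clones$value)),
              nrow(x$breakpoints), x$p_c))
  invisible(x)
}

#' Exact posterior by explicit partition enumeration (test oracle)
#'
#' Enumerates every one of the 2^(n-1) contiguous partitions of a short
#' sequence under the same product-partition model as
#' [segment_profile()] and accumulates the posterior mean per position and
#' the posterior changepoint probability per gap by direct summation.
#' Deliberately independent of the dynamic program so the two can check
#' each other; limited to n <= 14.
#'
#' @param y Numeric vector of observed values (single chromosome), or a
#'   `clone_profile` restricted to one chromosome (missing clones dropped).
#' @param p_c Prior changepoint probability per gap.
#' @param prior A [nig_prior()].
#' @return List: `post_mean` (length n), `cp_prob` (length n-1),
#'   `log_evidence`.
#' @export
enumerate_posterior_oracle <- function(y, p_c = 0.01, prior = nig_prior()) {
  if (is.data.frame(y)) {
    if (length(unique(y$chromosome)) != 1) {
      stop("oracle profiles must cover a single chromosome", call. = FALSE)
    }
    y <- y$value[!is.na(y$value)]
  }
  n <- length(y)
  if (n < 1) stop("empty profile", call. = FALSE)
  if (n > 14) stop("enumeration oracle is limited to n <= 14", call. = FALSE)
  lpc <- log(p_c)
  l1p <- log1p(-p_c)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  M <- matrix(-Inf, n, n)
  Mm <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    r <- .seg_row(i, n, cs, cs2, prior)
    M[i, i:n] <- r$logml
    Mm[i, i:n] <- r$mean
  }
  n_masks <- 2^(n - 1)
  logw <- numeric(n_masks)
  means <- matrix(NA_real_, n_masks, n)
  gaps <- matrix(0L, n_masks, max(n - 1, 0))
  for (m in seq_len(n_masks)) {
    bits <- if (n > 1) as.integer(bitwAnd(m - 1L, 2^(0:(n - 2))) > 0) else integer(0)
    ends <- c(which(bits == 1L), n)
    starts <- c(1L, which(bits == 1L) + 1L)
    k <- length(ends) - 1L
    logw[m] <- sum(M[cbind(starts, ends)]) + k * lpc + (n - 1 - k) * l1p
    for (s in seq_along(starts)) {
      means[m, starts[s]:ends[s]] <- Mm[starts[s], ends[s]]
    }
    if (n > 1) gaps[m, ] <- bits
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  list(post_mean = as.numeric(colSums(w * means)),
       cp_prob = if (n > 1) as.numeric(colSums(w * gaps)) else numeric(0),
       log_evidence = logsumexp(logw))
}

#' Ternary copy-number calls from a segmentation
#'
#' Assigns each observed clone the state of its reported segment: +1 if
#' the segment posterior mean exceeds `tau`, -1 if below `-tau`, else 0
#' (uncertain/neutral). Missing clones stay uncalled (NA).
#'
#' @param seg A `segmentation`.
#' @param tau Calling threshold in normalized (z) units, > 0; see
#'   [default_tau()].
#' @return A `state_calls` data.frame: clone_id, chromosome, start, end,
#'   state (-1/0/+1, NA for missing clones).
#' @export
call_states <- function(seg, tau) {
  stopifnot(inherits(seg, "segmentation"))
  if (!(is.numeric(tau) && length(tau) == 1 && tau > 0)) {
    stop("`tau` must be a single positive number", call. = FALSE)
  }
  df <- seg$clones[, c("clone_id", "chromosome", "start", "end")]
  m <- seg$clones$segment_mean
  df$state <- ifelse(is.na(m), NA_integer_,
                     ifelse(m > tau, 1L, ifelse(m < -tau, -1L, 0L)))
  structure(df, class = c("state_calls", "data.frame"),
            tau = tau, sample_id = attr(seg$clones, "sample_id"))
}

#' Default calling threshold from self-self spread
#'
#' tau = `multiplier` times the SD of the normalized self-self clone
#' values: a segment must sit `multiplier` noise-SDs away from the neutral
#' level before it is called. Three SDs is the conventional choice.
#'
#' @param selfself A numeric vector of self-self clone values, or a
#'   `clone_profile` of the normalized self-self array.
#' @param multiplier SD multiplier (default 3).
#' @return tau as a single number.
#' @export
default_tau <- function(selfself, multiplier = 3) {
  v <- if (is.data.frame(selfself)) selfself$value else selfself
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 self-self values", call. = FALSE)
  multiplier * stats::sd(v)
}
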