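#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero (so 72.5
#' becomes 73), matching how whole-percent frequencies are conventionally
#' printed. Base R's `round()` rounds ties to even, which is not what a
#' frequency table reader expects.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers (as doubles).
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_if_not_scalar_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) stop(sprintf("`%s` must be a single probability in %s0,1%s",
                        name, if (open_left) "(" else "[",
                        if (open_right) ")" else "]"), call. = FALSE)
  invisible(x)
}
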