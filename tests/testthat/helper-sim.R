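# Shared builders for small simulated inputs.

tiny_design <- function(n_regions = 2, clones_per_region = 10, n_blocks = 4,
                        replicates = 3, seed = 7) {
  make_array_design(n_regions, clones_per_region, n_blocks, replicates, seed)
}

# single-chromosome clone profile from a numeric vector
vec_profile <- function(y, chromosome = "1") {
  n <- length(y)
  structure(
    data.frame(clone_id = sprintf("c%03d", seq_len(n)),
               chromosome = chromosome,
               start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 999,
               value = y, stringsAsFactors = FALSE),
    class = c("clone_profile", "data.frame")
  )
}

# state_calls object from a plain state vector (for frequency tests)
vec_calls <- function(states, chromosome = "1") {
  n <- length(states)
  structure(
    data.frame(clone_id = sprintf("c%03d", seq_len(n)),
               chromosome = chromosome,
               start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 999,
               state = as.integer(states), stringsAsFactors = FALSE),
    class = c("state_calls", "data.frame")
  )
}

# gene table on one chromosome
gene_table <- function(symbols, chromosome, starts, ends, ...) {
  data.frame(symbol = symbols, chromosome = chromosome,
             start = starts, end = ends, ..., stringsAsFactors = FALSE)
}

# independent enumeration oracle for the upper-tail hypergeometric:
# direct sum of choose() products, no distribution function involved
hyper_tail_oracle <- function(x, K, n, N) {
  ks <- x:min(K, n)
  ks <- ks[n - ks <= N - K]
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
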