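# Readers for the shipped region/difference tables and generic TSV I/O.
# The extdata tables transcribe published cohort summaries: per-cohort
# imbalance-region tables (direction, frequency, gene count per region)
# and subtype/stage difference tables (two group entries plus the printed
# difference per region).

#' Path to a shipped fixture table
#'
#' @param name File name under the package's `extdata/` (e.g.
#'   "table1a.tsv"); with no argument, lists the available fixtures.
#' @return Full path, or a character vector of names.
#' @export
cgh_fixture <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "cghcohort")))
  }
  path <- system.file("extdata", name, package = "cghcohort")
  if (path == "") stop(sprintf("no fixture named '%s'", name), call. = FALSE)
  path
}

#' Read a cohort imbalance-region table
#'
#' Expects tab-separated columns: chromosome, cytoband, start, end,
#' size_mb, bac_n, direction, freq_pct, gene_n (1-based inclusive bp).
#'
#' @param path TSV file (e.g. `cgh_fixture("table1a.tsv")`).
#' @return A region data.frame.
#' @export
read_region_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chromosome = "character"))
  stopifnot(all(c("chromosome", "cytoband", "start", "end", "direction",
                  "freq_pct", "gene_n") %in% names(df)))
  stopifnot(all(df$start <= df$end),
            all(df$direction %in% c("gain", "loss")),
            all(df$freq_pct >= 0 & df$freq_pct <= 100))
  df
}

#' Read a two-group difference table
#'
#' Expects tab-separated columns: chromosome, cytoband, start, end,
#' size_mb, bac_n, a_direction, a_freq_pct, b_direction, b_freq_pct,
#' diff_pct, where the two groups are tumor subtypes (ADC vs SCC) or
#' stages (early vs late) and direction "none" marks no alteration.
#'
#' @param path TSV file (e.g. `cgh_fixture("table2a.tsv")`).
#' @return A data.frame.
#' @export
read_difference_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chromosome = "character"))
  stopifnot(all(c("chromosome", "cytoband", "start", "end",
                  "a_direction", "a_freq_pct", "b_direction", "b_freq_pct",
                  "diff_pct") %in% names(df)))
  stopifnot(all(df$a_direction %in% c("gain", "loss", "none")),
            all(df$b_direction %in% c("gain", "loss", "none")))
  df
}

#' Write a table as TSV
#' @param x data.frame.
#' @param path Output file.
#' @return Invisibly, `x`.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a spot table (TSV)
#' @param path TSV with columns spot_id, block, clone_id, log2ratio, qc_flag.
#' @return data.frame.
#' @export
read_spot_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("spot_id", "block", "clone_id", "log2ratio", "qc_flag")
                %in% names(df)))
  df
}
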