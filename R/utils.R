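# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# drop or keep a leading "chr" prefix on chromosome names
strip_chr_prefix <- function(x) sub("^chr", "", as.character(x))

stop_g4 <- function(..., call. = FALSE) stop(..., call. = call.)

check_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower)
    stop_g4(sprintf("'%s' must be a single number >= %s", name, lower))
  invisible(x)
}

#' Descriptive summary fields for a region group
#'
#' Computes the two report-precision descriptive statistics used throughout
#' the OQ-content summaries: the percentage of regions containing at least
#' one observed quadruplex (1 decimal place) and the mean number of OQs per
#' OQ-containing region (2 decimal places).
#'
#' @param n_regions Number of regions in the group.
#' @param n_with_oq Number of those regions containing at least one OQ.
#' @param total_oqs Total OQs located in the OQ-containing regions.
#' @return A list with `pct_with_oq` (rounded to 1 decimal),
#'   `mean_oq_per_oq_region` (rounded to 2 decimals), and the unrounded
#'   `pct_raw` and `mean_raw`.
#' @examples
#' oq_summary_stats(4, 2, 3)  # pct 50.0, mean 1.50
#' @export
oq_summary_stats <- function(n_regions, n_with_oq, total_oqs) {
  if (n_with_oq > n_regions)
    stop_g4("n_with_oq exceeds n_regions")
  pct <- if (n_regions > 0) 100 * n_with_oq / n_regions else NA_real_
  mn <- if (n_with_oq > 0) total_oqs / n_with_oq else NA_real_
  list(
    pct_with_oq = round(pct, 1),
    mean_oq_per_oq_region = round(mn, 2),
    pct_raw = pct,
    mean_raw = mn
  )
}
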