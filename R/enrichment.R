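#' Hypergeometric upper-tail enrichment probability
#'
#' Probability of observing at least `k` successes in `n` draws without
#' replacement from a universe of `N` items of which `K` are successes:
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' Terms are accumulated in log space so universes of ~50,000 genes with
#' p-values far below double underflow are handled; the log-scale value is
#' returned alongside `p`.
#'
#' @param N Universe size.
#' @param K Successes in the universe.
#' @param n Sample size.
#' @param k Successes in the sample.
#' @param test Label stored in the result.
#' @return Object of class `g4_enrichment`: list with `test`, `N`, `K`,
#'   `n`, `k`, `p`, `log_p` (natural log).
#' @export
hypergeom_upper_tail <- function(N, K, n, k, test = "hypergeometric_upper_tail") {
  for (nm in c("N", "K", "n", "k")) check_scalar_number(get(nm), nm, lower = 0)
  if (K > N || n > N) stop_g4("require K <= N and n <= N")
  if (k > min(n, K) || k < max(0, n + K - N))
    stop_g4(sprintf("k = %d outside support [%d, %d]", k,
                    max(0, n + K - N), min(n, K)))
  i <- seq.int(k, min(n, K))
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  log_p <- min(logsumexp(log_terms), 0)
  structure(
    list(test = test, N = N, K = K, n = n, k = k,
         p = exp(log_p), log_p = log_p),
    class = "g4_enrichment"
  )
}

#' @export
print.g4_enrichment <- function(x, ...) {
  cat(sprintf("%s: N=%d K=%d n=%d k=%d  p=%.4g (log10 p=%.2f)\n",
              x$test, x$N, x$K, x$n, x$k, x$p, x$log_p / log(10)))
  invisible(x)
}

#' Wilcoxon rank-sum test with tie-corrected normal approximation
#'
#' Two-sample rank-sum test using midranks for ties. The statistic is the
#' Mann-Whitney form \eqn{W = \sum \mathrm{rank}(x) - n_1(n_1+1)/2}, so
#' \eqn{0 \le W \le n_1 n_2}. For tie-free samples with
#' \eqn{n_1 + n_2 \le 20} the p-value is exact, by enumeration of all
#' \eqn{\binom{n_1+n_2}{n_1}} rank assignments; otherwise a normal
#' approximation with the tie-corrected variance
#' \eqn{n_1 n_2/12\,[(N+1) - \sum(t^3-t)/(N(N-1))]} and a 0.5 continuity
#' correction is used. Two-sided p-values are twice the smaller tail,
#' capped at 1.
#'
#' @param x,y Numeric samples (x is the group of interest, e.g. DE).
#' @param alternative `"two_sided"`, `"greater"` (x tends larger), or
#'   `"less"`.
#' @param method `"auto"` (default rule above), or force `"exact"` /
#'   `"normal_approx"`. Exact requires tie-free samples with
#'   `n1 + n2 <= 20`.
#' @return Object of class `g4_ranksum`: list with `W`, `p`, `n1`, `n2`,
#'   `ties_present`, `method` (`"exact"` or `"normal_approx"`),
#'   `alternative`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two_sided", "greater", "less"),
                          method = c("auto", "exact", "normal_approx")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(x) == 0L || length(y) == 0L)
    stop_g4("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties_present <- anyDuplicated(c(x, y)) > 0L
  use_exact <- if (method == "auto") !ties_present && N <= 20L
    else method == "exact"
  if (use_exact && (ties_present || N > 20L))
    stop_g4("exact method requires tie-free samples with n1 + n2 <= 20")
  if (use_exact) {
    method <- "exact"
    w_all <- colSums(matrix(seq_len(N)[utils::combn(N, n1)], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p_g <- mean(w_all >= W)
    p_l <- mean(w_all <= W)
  } else {
    method <- "normal_approx"
    # tie-corrected variance; 0.5 continuity correction on each tail
    mu <- n1 * n2 / 2
    tab <- table(r)
    tie_term <- sum(tab^3 - tab)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p_g <- p_l <- 1
    } else {
      s <- sqrt(sigma2)
      p_g <- stats::pnorm((W - mu - 0.5) / s, lower.tail = FALSE)
      p_l <- stats::pnorm((W - mu + 0.5) / s)
    }
  }
  p <- switch(alternative,
              two_sided = min(1, 2 * min(p_g, p_l)),
              greater = p_g,
              less = p_l)
  structure(
    list(W = W, p = p, n1 = n1, n2 = n2, ties_present = ties_present,
         method = method, alternative = alternative),
    class = "g4_ranksum"
  )
}

#' @export
print.g4_ranksum <- function(x, ...) {
  cat(sprintf("rank-sum (%s, %s): W=%s  p=%.4g  (n1=%d, n2=%d%s)\n",
              x$method, x$alternative, format(x$W, big.mark = ","), x$p,
              x$n1, x$n2, if (x$ties_present) ", ties" else ""))
  invisible(x)
}

group_counts <- function(assignments, partition, region_class, group,
                         restrict_to_regions = TRUE) {
  a <- assignments[assignments$region_class == region_class, , drop = FALSE]
  ids <- partition$groups[[group]]
  if (is.null(ids)) stop_g4("unknown group: ", group)
  if (restrict_to_regions) {
    ids <- intersect(ids, a$region_id)
  } else {
    unknown <- setdiff(ids, a$region_id)
    if (length(unknown))
      stop_g4("group '", group, "' references unknown region ids: ",
              paste(utils::head(unknown, 5), collapse = ", "))
  }
  a$oq_count[match(ids, a$region_id)]
}

#' Summarize OQ content per gene group
#'
#' For each group, reports the number of regions, how many contain at least
#' one OQ, the total OQ count within those OQ-containing regions, the
#' percentage of regions with an OQ (1 decimal) and the mean OQs per
#' OQ-containing region (2 decimals); unrounded values are kept in
#' `pct_raw`/`mean_raw`.
#'
#' @param assignments `data.frame` from [assign_contained()] covering the
#'   region class.
#' @param partition `g4_partition` from [partition_genes()].
#' @param region_class `"promoter"` or `"gene"`.
#' @param groups Group names to summarize (default: all partition groups
#'   plus `"all"` for the whole region universe).
#' @param restrict_to_regions If `TRUE` (default), group ids without a
#'   region of this class (e.g. promoters dropped by edge clipping) are
#'   silently excluded; if `FALSE`, they raise an error listing the ids.
#' @return `data.frame`, one row per group.
#' @export
summarize_oq_content <- function(assignments, partition, region_class,
                                 groups = c("all", names(partition$groups)),
                                 restrict_to_regions = TRUE) {
  a <- assignments[assignments$region_class == region_class, , drop = FALSE]
  if (nrow(a) == 0L) stop_g4("no assignments for region class ", region_class)
  rows <- lapply(groups, function(g) {
    counts <- if (g == "all") a$oq_count
      else group_counts(assignments, partition, region_class, g,
                        restrict_to_regions)
    st <- oq_summary_stats(length(counts), sum(counts >= 1),
                           sum(counts[counts >= 1]))
    data.frame(region_class = region_class, group = g,
               n_regions = length(counts), n_with_oq = sum(counts >= 1),
               total_oqs_in_oq_regions = sum(counts[counts >= 1]),
               pct_with_oq = st$pct_with_oq,
               mean_oq_per_oq_region = st$mean_oq_per_oq_region,
               pct_raw = st$pct_raw, mean_raw = st$mean_raw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Presence enrichment of OQs in a gene group
#'
#' Hypergeometric test of whether regions of a gene group are more likely
#' to contain at least one OQ than the region universe (the genomic
#' background): `N` = all regions of the class, `K` = those with an OQ,
#' `n` = group size, `k` = group regions with an OQ.
#'
#' @inheritParams summarize_oq_content
#' @param group Group name, e.g. `"DE"`.
#' @return `g4_enrichment`.
#' @export
presence_enrichment <- function(assignments, partition, region_class, group,
                                restrict_to_regions = TRUE) {
  a <- assignments[assignments$region_class == region_class, , drop = FALSE]
  counts <- group_counts(assignments, partition, region_class, group,
                         restrict_to_regions)
  hypergeom_upper_tail(
    N = nrow(a), K = sum(a$oq_count >= 1),
    n = length(counts), k = sum(counts >= 1),
    test = paste0("presence_enrichment[", region_class, ":", group, "]")
  )
}

#' Compare OQ counts per region between two gene groups
#'
#' Rank-sum comparison of the per-region OQ counts of two groups. By
#' default only OQ-containing regions enter the comparison (the reported
#' group means are means over OQ-containing regions); set
#' `positive_only = FALSE` to include zero-count regions.
#'
#' @inheritParams summarize_oq_content
#' @param group_a,group_b Group names; `group_a` is the first sample.
#' @param positive_only Restrict to regions with `oq_count >= 1`.
#' @param alternative Passed to [rank_sum_test()].
#' @return `g4_ranksum`.
#' @export
count_comparison <- function(assignments, partition, region_class,
                             group_a, group_b, positive_only = TRUE,
                             alternative = "two_sided",
                             restrict_to_regions = TRUE) {
  ca <- group_counts(assignments, partition, region_class, group_a,
                     restrict_to_regions)
  cb <- group_counts(assignments, partition, region_class, group_b,
                     restrict_to_regions)
  if (positive_only) {
    ca <- ca[ca >= 1]; cb <- cb[cb >= 1]
  }
  if (length(ca) == 0L || length(cb) == 0L)
    stop_g4("a group has no OQ-containing region of class ", region_class)
  rank_sum_test(ca, cb, alternative = alternative)
}

#' Compare gene lengths between groups (length confound check)
#'
#' DE genes can differ in length from non-DE genes, which confounds
#' gene-body OQ counts; this compares annotated gene lengths between two
#' groups, restricted to genes whose gene-body region contains at least one
#' OQ, and reports the group mean lengths alongside the rank-sum test.
#'
#' @param genes `GRanges` of genes with `gene_id`.
#' @inheritParams count_comparison
#' @return List with `ranksum` (`g4_ranksum`), `mean_length_a`,
#'   `mean_length_b`, `n_a`, `n_b`.
#' @export
length_comparison <- function(genes, assignments, partition,
                              group_a = "DE", group_b = "nonDE",
                              region_class = "gene",
                              alternative = "two_sided") {
  a <- assignments[assignments$region_class == region_class, , drop = FALSE]
  with_oq <- a$region_id[a$oq_count >= 1]
  len <- GenomicRanges::width(genes)
  names(len) <- genes$gene_id
  la <- len[intersect(intersect(partition$groups[[group_a]], with_oq), names(len))]
  lb <- len[intersect(intersect(partition$groups[[group_b]], with_oq), names(len))]
  if (length(la) == 0L || length(lb) == 0L)
    stop_g4("a group has no OQ-containing gene")
  list(
    ranksum = rank_sum_test(as.numeric(la), as.numeric(lb),
                            alternative = alternative),
    mean_length_a = mean(la), mean_length_b = mean(lb),
    n_a = length(la), n_b = length(lb)
  )
}

#' Over-representation analysis with Benjamini-Hochberg correction
#'
#' Generic term over-representation: for each term gene set, an upper-tail
#' hypergeometric test of the overlap with the query set against the
#' universe, followed by Benjamini-Hochberg adjustment across terms. Term
#' gene sets and the query are reconciled to the universe first.
#'
#' @param term_sets Named list of gene-id vectors, one per term.
#' @param query Gene-id vector (e.g. upregulated DE genes).
#' @param universe Gene-id vector of all analyzed genes.
#' @return `data.frame` with one row per term: `term`, `N`, `K`, `n`, `k`,
#'   `p`, `padj`.
#' @export
ora_with_bh <- function(term_sets, query, universe) {
  universe <- unique(as.character(universe))
  query <- intersect(unique(as.character(query)), universe)
  if (length(query) == 0L) stop_g4("query is empty after reconciliation")
  if (length(universe) == 0L) stop_g4("universe is empty")
  if (is.null(names(term_sets)) || !length(term_sets))
    stop_g4("term_sets must be a non-empty named list")
  rows <- lapply(names(term_sets), function(tm) {
    tg <- intersect(unique(as.character(term_sets[[tm]])), universe)
    res <- hypergeom_upper_tail(N = length(universe), K = length(tg),
                                n = length(query),
                                k = length(intersect(query, tg)))
    data.frame(term = tm, N = res$N, K = res$K, n = res$n, k = res$k,
               p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Read term gene sets from TSV or GMT
#'
#' Term mappings are accepted as a two-column TSV (`term`, `gene_id`, no
#' header) or as GMT (term, description, then gene ids, tab-separated).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gmt"`.
#' @return Named list of gene-id vectors.
#' @export
read_term_sets <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop_g4("term TSV needs two columns (term, gene_id)")
    split(as.character(df[[2L]]), df[[1L]])
  } else {
    lines <- strsplit(readLines(path), "\t")
    stats::setNames(lapply(lines, function(f) unique(f[-(1:2)])),
                    vapply(lines, `[[`, "", 1L))
  }
}
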