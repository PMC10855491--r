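# Shared fixtures and independent oracles.

# quick GRanges builder from 0-based half-open coordinates
gr0 <- function(chrom, start0, end, strand = "*", id = NULL) {
  g <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start = start0 + 1, end = end),
                              strand = strand)
  if (!is.null(id)) g$gene_id <- id
  g
}

# brute-force all-pairs containment oracle (quadratic scan)
brute_contained_counts <- function(regions, oqs) {
  rc <- as.character(GenomicRanges::seqnames(regions))
  rs <- GenomicRanges::start(regions); re <- GenomicRanges::end(regions)
  oc <- as.character(GenomicRanges::seqnames(oqs))
  os <- GenomicRanges::start(oqs); oe <- GenomicRanges::end(oqs)
  vapply(seq_along(regions), function(i)
    sum(oc == rc[i] & os >= rs[i] & oe <= re[i]), integer(1))
}

# exhaustive hypergeometric upper-tail oracle: enumerate all C(N, n) draws
# from an explicit 0/1 universe and count those with >= k successes
enum_hyper_upper <- function(N, K, n, k) {
  universe <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  mean(colSums(matrix(universe[draws], nrow = n)) >= k)
}

# random tiny annotation written as the TSV dialect
write_genes_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_bed3 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

write_de_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

# a small deterministic generated dataset shared by several tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_g4_dataset(synthetic_config(seed = 42, n_genes = 600,
                                                     chrom_length = 1e7))
    cache
  }
})

sim_genes_gr <- function(sim) {
  gr0(sim$genes$chrom, sim$genes$start0, sim$genes$end,
      strand = sim$genes$strand, id = sim$genes$gene_id)
}

sim_consensus_gr <- function(sim) {
  gr0(sim$consensus$chrom, sim$consensus$start1 - 1, sim$consensus$end)
}
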