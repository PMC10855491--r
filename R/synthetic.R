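#' Configuration for the synthetic G4/DE dataset generator
#'
#' Builds and validates the parameter set for [simulate_g4_dataset()] /
#' [generate_g4_dataset()]. The generator emulates the statistical structure
#' of a G4-Seq x RNA-seq study: a small genome with non-overlapping genes of
#' log-normal length on both strands, observed-quadruplex (OQ) intervals
#' placed at a baseline Poisson density per kb, a multiplicative density
#' enrichment `rho` in the promoters and bodies of the differentially
#' expressed (DE) gene subset, and a DESeq2-shaped DE table whose
#' fold-changes span the 2-, 5- and 10-fold tiers.
#'
#' @param seed RNG seed (single integer; drives every random draw).
#' @param n_genes Number of genes.
#' @param n_chroms,chrom_length Number of chromosomes and their common
#'   length (bp).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length
#'   parameters (bp scale).
#' @param gene_length_range Truncation bounds for gene length (bp).
#' @param strand_prob Probability of the `+` strand.
#' @param prob_protein_coding Probability a gene is protein-coding.
#' @param window Promoter width (bp).
#' @param lambda0 Baseline OQ density, expected OQs per kb.
#' @param rho Multiplicative OQ-density enrichment in DE-gene promoters and
#'   gene bodies; `rho = 1` is the null.
#' @param oq_length_range OQ interval length bounds (bp).
#' @param de_fraction Fraction of genes that are DE.
#' @param prob_up Probability a DE gene is upregulated.
#' @param tier_probs Probabilities that a DE gene's |log2 fold-change| falls
#'   below 2-fold, in [2,5), in [5,10), or at >= 10-fold.
#' @param decoy_rate Density (per kb of intergenic space) of
#'   condition-private decoy intervals added to each stabilizer BED; decoys
#'   never survive the consensus intersection.
#' @param alpha Adjusted-p threshold separating DE from non-DE padj draws.
#' @return Validated list of class `g4_sim_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 2000L,
                             n_chroms = 4L,
                             chrom_length = 2.5e7,
                             gene_length_meanlog = log(8000),
                             gene_length_sdlog = 1.0,
                             gene_length_range = c(1000, 100000),
                             strand_prob = 0.5,
                             prob_protein_coding = 0.45,
                             window = 1000L,
                             lambda0 = 0.5,
                             rho = 3,
                             oq_length_range = c(15L, 50L),
                             de_fraction = 0.15,
                             prob_up = 0.543,
                             tier_probs = c(sub2 = 0.80, t2 = 0.145,
                                            t5 = 0.04, t10 = 0.015),
                             decoy_rate = 0.25,
                             alpha = 0.05) {
  check_scalar_number(lambda0, "lambda0", lower = 1e-9)
  check_scalar_number(rho, "rho", lower = 0)
  if (de_fraction <= 0 || de_fraction >= 1)
    stop_g4("de_fraction must be in (0, 1)")
  if (oq_length_range[1] < 1 || oq_length_range[2] < oq_length_range[1])
    stop_g4("invalid oq_length_range")
  if (abs(sum(tier_probs) - 1) > 1e-8)
    stop_g4("tier_probs must sum to 1")
  structure(as.list(environment()), class = "g4_sim_config")
}

# truncated log-normal gene lengths by rejection
rlnorm_trunc <- function(n, meanlog, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2L * (n - length(out)) + 10L, meanlog, sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  round(out[seq_len(n)])
}

# Place `counts[i]` intervals uniformly and non-overlapping (>= 1 bp apart)
# inside each region [rstart[i], rend[i]] (1-based closed), vectorized over
# regions. For region i with k intervals of lengths l_1..l_k, the start of
# the j-th interval is rstart + c_j + sum_{m<j}(l_m + 1) where c_1<=..<=c_k
# are k sorted uniform draws from {0..slack}, slack = L - sum(l) - (k-1).
place_many <- function(rstart, rend, counts, len_range) {
  K <- sum(counts)
  if (K == 0L)
    return(data.frame(region = integer(0), start1 = integer(0),
                      end = integer(0)))
  present <- counts > 0L
  reg <- rep(seq_along(counts), counts)
  lens <- sample(seq.int(len_range[1], len_range[2]), K, replace = TRUE)
  sumlens <- rowsum(lens, reg)[, 1]
  islack <- (rend - rstart + 1)[present] - sumlens - (counts[present] - 1L)
  if (any(islack < 0))
    stop_g4("cannot place ", max(counts), " intervals in a region of ",
            min((rend - rstart + 1)[present][islack < 0]),
            " bp; lower lambda0/rho or oq lengths")
  cuts <- floor(stats::runif(K) * (rep(islack, counts[present]) + 1))
  o <- order(reg, cuts)
  cuts <- cuts[o]
  ex <- cumsum(lens + 1) - (lens + 1)   # exclusive within-run cumsum base
  prevlen <- ex - rep(ex[!duplicated(reg)], counts[present])
  start1 <- rstart[reg] + cuts + prevlen
  data.frame(region = reg, start1 = as.integer(start1),
             end = as.integer(start1 + lens - 1L))
}

#' Simulate a G4/DE dataset in memory
#'
#' Generates the full synthetic dataset described in [synthetic_config()]
#' and returns it as in-memory tables plus the planted ground truth. Genes
#' are placed without overlap and with inter-gene gaps of at least
#' `2*window + 2` bp, so promoters and gene bodies are pairwise disjoint
#' and every planted per-region OQ count is exactly recoverable by strict
#' containment. Planted OQs keep a 1 bp margin from region boundaries so no
#' two planted intervals are ever adjacent across the promoter/body
#' junction. Each stabilizer-condition set is the planted (consensus) OQs
#' plus condition-private decoys confined to intergenic space.
#'
#' @param config `g4_sim_config` from [synthetic_config()].
#' @return List of class `g4_sim` with elements `genes` (data.frame:
#'   gene_id, chrom, start0, end, strand, biotype, length, is_de),
#'   `de_table`, `oq_kplus`, `oq_pds`, `consensus` (data.frames: chrom,
#'   start0, end), `chrom_sizes` (named vector), and `truth` (list: seed,
#'   run_id, params, per-gene planted counts, totals).
#' @export
simulate_g4_dataset <- function(config) {
  stopifnot(inherits(config, "g4_sim_config"))
  set.seed(config$seed)
  cfg <- config
  w <- as.integer(cfg$window)
  min_gap <- 2L * w + 2L

  lens <- rlnorm_trunc(cfg$n_genes, cfg$gene_length_meanlog,
                       cfg$gene_length_sdlog, cfg$gene_length_range)
  chrom_of <- rep(seq_len(cfg$n_chroms), length.out = cfg$n_genes)
  chrom_names <- sprintf("chrS%d", seq_len(cfg$n_chroms))
  starts <- integer(cfg$n_genes)
  for (ci in seq_len(cfg$n_chroms)) {
    idx <- which(chrom_of == ci)
    m <- length(idx)
    if (m == 0L) next
    islack <- cfg$chrom_length - sum(lens[idx]) - (m + 1L) * min_gap
    if (islack < 0)
      stop_g4("gene placement infeasible on chromosome ", ci,
              ": increase chrom_length or reduce n_genes/gene lengths")
    cuts <- sort(sample.int(islack + 1L, m, replace = TRUE) - 1L)
    gaps <- min_gap + diff(c(0L, cuts, islack))
    s <- integer(m)
    pos <- 0L
    for (j in seq_len(m)) {
      s[j] <- pos + gaps[j] + 1L
      pos <- s[j] + lens[idx[j]] - 1L
    }
    starts[idx] <- s
  }
  ord <- order(chrom_of, starts)
  genes <- data.frame(
    gene_id = sprintf("G%05d", seq_len(cfg$n_genes)),
    chrom = chrom_names[chrom_of[ord]],
    start1 = starts[ord],
    end = starts[ord] + lens[ord] - 1L,
    strand = ifelse(stats::runif(cfg$n_genes) < cfg$strand_prob, "+", "-"),
    biotype = ifelse(stats::runif(cfg$n_genes) < cfg$prob_protein_coding,
                     "protein_coding", "non_coding"),
    stringsAsFactors = FALSE
  )
  genes$length <- genes$end - genes$start1 + 1L

  n_de <- round(cfg$de_fraction * cfg$n_genes)
  de_idx <- sort(sample.int(cfg$n_genes, n_de))
  genes$is_de <- seq_len(cfg$n_genes) %in% de_idx

  # DE table
  lfc <- stats::rnorm(cfg$n_genes, 0, 0.25)
  tier_lo <- c(0.05, 1, log2(5), log2(10))
  tier_hi <- c(0.999, log2(5), log2(10), 5)
  tcat <- sample.int(4L, n_de, replace = TRUE, prob = cfg$tier_probs)
  mag <- stats::runif(n_de, tier_lo[tcat], tier_hi[tcat])
  sgn <- ifelse(stats::runif(n_de) < cfg$prob_up, 1, -1)
  lfc[de_idx] <- sgn * mag
  padj <- stats::runif(cfg$n_genes, cfg$alpha * 1.02, 1)
  padj[de_idx] <- stats::runif(n_de, 1e-8, cfg$alpha * 0.98)
  de_table <- data.frame(
    gene_id = genes$gene_id,
    log2fc = lfc,
    pvalue = padj * stats::runif(cfg$n_genes, 0.05, 1),
    padj = padj,
    stringsAsFactors = FALSE
  )

  # promoter coordinates (1-based closed), strand-aware
  plus <- genes$strand == "+"
  prom_s <- ifelse(plus, genes$start1 - w, genes$end + 1L)
  prom_e <- prom_s + w - 1L

  # plant OQs: Poisson per region (promoters stacked before gene bodies),
  # placed with a 1 bp margin inside each region so no planted interval is
  # ever adjacent to one in a neighbouring region
  mult <- ifelse(genes$is_de, cfg$rho, 1)
  rs <- c(prom_s, genes$start1)
  re <- c(prom_e, genes$end)
  rate <- cfg$lambda0 * rep(mult, 2L) * (re - rs + 1) / 1000
  counts <- stats::rpois(length(rate), rate)
  planted <- place_many(rs + 1L, re - 1L, counts, cfg$oq_length_range)
  prom_oq <- counts[seq_len(cfg$n_genes)]
  body_oq <- counts[cfg$n_genes + seq_len(cfg$n_genes)]
  chrom_all <- rep(genes$chrom, 2L)
  consensus <- data.frame(chrom = chrom_all[planted$region],
                          start1 = planted$start1, end = planted$end,
                          stringsAsFactors = FALSE)
  consensus <- consensus[order(consensus$chrom, consensus$start1), ]
  rownames(consensus) <- NULL

  # condition-private decoys in intergenic free space
  block_s <- ifelse(plus, prom_s, genes$start1)
  block_e <- ifelse(plus, genes$end, prom_e)
  free_s <- free_e <- integer(0)
  free_chrom <- character(0)
  for (ci in seq_len(cfg$n_chroms)) {
    sel <- genes$chrom == chrom_names[ci]
    fs <- c(1L, block_e[sel] + 2L)
    fe <- c(block_s[sel] - 2L, cfg$chrom_length)
    ok <- fe - fs + 1 >= cfg$oq_length_range[2] + 2L
    free_s <- c(free_s, fs[ok]); free_e <- c(free_e, fe[ok])
    free_chrom <- c(free_chrom, rep(chrom_names[ci], sum(ok)))
  }
  dcounts <- stats::rpois(length(free_s),
                          cfg$decoy_rate * (free_e - free_s + 1) / 1000)
  dplaced <- place_many(free_s + 1L, free_e - 1L, dcounts,
                        cfg$oq_length_range)
  decoys <- data.frame(chrom = free_chrom[dplaced$region],
                       start1 = dplaced$start1, end = dplaced$end,
                       stringsAsFactors = FALSE)
  to_k <- seq_len(nrow(decoys)) %% 2L == 1L
  mk_bed <- function(extra) {
    df <- rbind(consensus, extra)
    df <- df[order(df$chrom, df$start1), ]
    rownames(df) <- NULL
    df
  }
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                 chrom_names)

  truth <- list(
    run_id = sprintf("g4sim-seed%d", cfg$seed),
    seed = cfg$seed,
    params = unclass(cfg),
    genes = data.frame(gene_id = genes$gene_id, is_de = genes$is_de,
                       length = genes$length,
                       promoter_oq = prom_oq, body_oq = body_oq,
                       log2fc = lfc, padj = padj,
                       stringsAsFactors = FALSE),
    totals = list(
      n_genes = cfg$n_genes,
      n_de = n_de,
      n_consensus = nrow(consensus),
      n_decoy_kplus = sum(to_k),
      n_decoy_pds = sum(!to_k),
      mean_promoter_oq_de = mean(prom_oq[genes$is_de]),
      mean_promoter_oq_nonde = mean(prom_oq[!genes$is_de])
    )
  )

  structure(list(
    genes = data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                       start0 = genes$start1 - 1L, end = genes$end,
                       strand = genes$strand, biotype = genes$biotype,
                       length = genes$length, is_de = genes$is_de,
                       stringsAsFactors = FALSE),
    de_table = de_table,
    oq_kplus = mk_bed(decoys[to_k, , drop = FALSE]),
    oq_pds = mk_bed(decoys[!to_k, , drop = FALSE]),
    consensus = consensus,
    chrom_sizes = chrom_sizes,
    truth = truth
  ), class = "g4_sim")
}

#' Generate a synthetic dataset on disk
#'
#' Runs [simulate_g4_dataset()] and writes the file set consumed by the
#' pipeline readers: `genes.tsv` (TSV annotation dialect), `oq_kplus.bed`
#' and `oq_pds.bed` (BED3), `de_table.tsv`, `chrom_sizes.tsv`, and
#' `truth.json` with every planted quantity. Every file carries the seed in
#' a header comment; output is byte-identical across reruns with the same
#' config.
#'
#' @param config `g4_sim_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the `g4_sim` object and the named file
#'   `paths`.
#' @export
generate_g4_dataset <- function(config, outdir) {
  sim <- simulate_g4_dataset(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# seed=%d", config$seed)
  paths <- list(
    genes = file.path(outdir, "genes.tsv"),
    oq_kplus = file.path(outdir, "oq_kplus.bed"),
    oq_pds = file.path(outdir, "oq_pds.bed"),
    de_table = file.path(outdir, "de_table.tsv"),
    chrom_sizes = file.path(outdir, "chrom_sizes.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_tsv_hdr <- function(df, path, col.names = TRUE) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  }
  write_tsv_hdr(sim$genes[c("gene_id", "chrom", "start0", "end",
                            "strand", "biotype")], paths$genes)
  bed <- function(df) data.frame(chrom = df$chrom, start = df$start1 - 1L,
                                 end = df$end)
  write_tsv_hdr(bed(sim$oq_kplus), paths$oq_kplus, col.names = FALSE)
  write_tsv_hdr(bed(sim$oq_pds), paths$oq_pds, col.names = FALSE)
  write_tsv_hdr(sim$de_table, paths$de_table)
  write_tsv_hdr(data.frame(chrom = names(sim$chrom_sizes),
                           length = unname(sim$chrom_sizes)),
                paths$chrom_sizes)
  sim$truth$input_checksums <-
    unname_md5(unlist(paths[c("genes", "oq_kplus", "oq_pds", "de_table")]))
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(sim = sim, paths = paths))
}

# named list (not vector) so the checksums serialize as a JSON object
unname_md5 <- function(paths) {
  md5 <- tools::md5sum(paths)
  stats::setNames(as.list(unname(md5)), basename(names(md5)))
}

#' Compare a pipeline report against planted truth
#'
#' Validates a pipeline run on generated data against the generator's
#' `truth.json`: input checksums must identify the same run, stage and
#' group counts must match exactly, and enrichment-test directions must
#' match the planted enrichment (`rho`). Means are compared exactly since
#' both sides are computed from the same integer counts.
#'
#' @param report Pipeline report list (or path to `report.json`).
#' @param truth Truth list (or path to `truth.json`).
#' @return List of class `g4_recovery`: `ok` (logical) and `mismatches`
#'   (character vector of human-readable discrepancies).
#' @export
recover_truth <- function(report, truth) {
  if (is.character(report)) report <- jsonlite::read_json(report, simplifyVector = TRUE)
  if (is.character(truth)) truth <- jsonlite::read_json(truth, simplifyVector = TRUE)
  mism <- character(0)
  note <- function(...) mism <<- c(mism, sprintf(...))

  # run identity is keyed on the annotation and DE table; the OQ BEDs are
  # data under validation, so corrupting them yields count mismatches below
  # rather than a run-identity error
  rc <- report$input_checksums
  tc <- truth$input_checksums
  if (!is.null(rc) && !is.null(tc)) {
    shared <- intersect(intersect(names(tc), names(rc)),
                        c("genes.tsv", "de_table.tsv"))
    if (length(shared) == 0L || !identical(unlist(rc[shared]), unlist(tc[shared])))
      stop_g4("report and truth come from different runs (checksum mismatch)")
  }

  tg <- truth$genes
  expect_eq <- function(what, got, want) {
    if (!isTRUE(all.equal(as.numeric(got), as.numeric(want), tolerance = 0)))
      note("%s: pipeline %s != planted %s", what, format(got), format(want))
  }
  expect_eq("consensus OQ count", report$stages$n_consensus_oqs,
            truth$totals$n_consensus)
  expect_eq("n_genes", report$stages$n_genes, truth$totals$n_genes)

  sm <- report$summaries
  chk_group <- function(class, group, sel, planted) {
    row <- sm[sm$region_class == class & sm$group == group, , drop = FALSE]
    if (nrow(row) != 1L) { note("missing summary %s/%s", class, group); return() }
    expect_eq(paste(class, group, "n_regions"), row$n_regions, sum(sel))
    expect_eq(paste(class, group, "n_with_oq"), row$n_with_oq,
              sum(planted[sel] >= 1))
    expect_eq(paste(class, group, "total_oqs"),
              row$total_oqs_in_oq_regions, sum(planted[sel][planted[sel] >= 1]))
  }
  chk_group("promoter", "DE", tg$is_de, tg$promoter_oq)
  chk_group("promoter", "nonDE", !tg$is_de, tg$promoter_oq)
  chk_group("gene", "DE", tg$is_de, tg$body_oq)
  chk_group("gene", "nonDE", !tg$is_de, tg$body_oq)

  rho <- truth$params$rho
  if (!is.null(rho) && rho != 1) {
    for (tst in c("promoter_counts_DE_vs_nonDE", "gene_counts_DE_vs_nonDE")) {
      t_ <- report$tests[[tst]]
      if (is.null(t_)) { note("missing test %s", tst); next }
      expected_larger <- rho > 1
      observed_larger <- t_$W > t_$n1 * t_$n2 / 2
      if (expected_larger != observed_larger)
        note("%s: observed direction disagrees with planted rho=%g", tst, rho)
    }
  }
  structure(list(ok = length(mism) == 0L, mismatches = mism),
            class = "g4_recovery")
}

#' @export
print.g4_recovery <- function(x, ...) {
  if (x$ok) cat("recovery OK: pipeline output matches planted truth\n")
  else cat("recovery FAILED:\n", paste(" -", x$mismatches, collapse = "\n"), "\n")
  invisible(x)
}
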