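#' Run the full G4/expression association analysis
#'
#' End-to-end orchestration: read the gene annotation, derive promoters and
#' gene bodies, build the consensus OQ catalog from the two stabilizer
#' conditions, assign OQs to regions by strict containment, stratify genes
#' by DE status and fold-change tier, and compute the descriptive summaries
#' and enrichment statistics for the requested region classes. Optionally
#' tallies user-supplied gene lists (e.g. transcription factors, oncogenes)
#' against the DE results and writes a machine-readable report.
#'
#' @param annotation Path to the gene annotation.
#' @param dialect Annotation dialect: `"tsv"`, `"gtf"`, or `"gff3"`.
#' @param oq_kplus,oq_pds Paths to the two condition BED files.
#' @param de_table Path to the DE results TSV.
#' @param chrom_sizes Named numeric vector of chromosome lengths, or path
#'   to a two-column TSV (`chrom`, `length`). If `NULL`, lengths are taken
#'   as the per-chromosome maximum annotated end plus the promoter window
#'   (promoters then never clip at the right edge).
#' @param window Promoter width in bp (default 1000).
#' @param alpha DE significance threshold on adjusted p (default 0.05).
#' @param tiers Fold-change tiers (default `c(2, 5, 10)`).
#' @param chroms Optional chromosome filter.
#' @param strand_policy `"ignore"` or `"match"` for OQ-to-region
#'   assignment.
#' @param consensus_mode `"intersect"` or `"kplus-anchored"`.
#' @param region_class `"both"`, `"promoter"`, or `"gene"`.
#' @param gene_lists Optional named character vector of gene-list file
#'   paths to tally.
#' @param strip_chr Normalize away `"chr"` prefixes in the annotation.
#' @param outdir If non-NULL, report and tables are written there.
#' @param verbose Log stage counts to stderr.
#' @return The report: a list with `version`, `config`, `input_checksums`,
#'   `stages`, `partition_sizes`, `summaries` (data.frame), `tests`,
#'   and optionally `gene_set_tallies`. Reruns on identical inputs produce
#'   identical reports (no timestamps).
#' @export
run_g4_analysis <- function(annotation, oq_kplus, oq_pds, de_table,
                            dialect = c("tsv", "gtf", "gff3"),
                            chrom_sizes = NULL,
                            window = 1000, alpha = 0.05, tiers = c(2, 5, 10),
                            chroms = NULL,
                            strand_policy = c("ignore", "match"),
                            consensus_mode = c("intersect", "kplus-anchored"),
                            region_class = c("both", "promoter", "gene"),
                            gene_lists = NULL, strip_chr = FALSE,
                            outdir = NULL, verbose = TRUE) {
  dialect <- match.arg(dialect)
  strand_policy <- match.arg(strand_policy)
  consensus_mode <- match.arg(consensus_mode)
  region_class <- match.arg(region_class)
  log_msg <- function(...) if (verbose) message("[g4assoc] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_g4(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }
  for (p in c(annotation, oq_kplus, oq_pds, de_table))
    if (!file.exists(p)) stop_g4("input file not found: ", p)

  genes <- stage("annotations",
                 read_gene_annotation(annotation, dialect = dialect,
                                      chrom_filter = chroms,
                                      strip_chr = strip_chr))
  log_msg("genes read: %d", length(genes))

  if (is.character(chrom_sizes)) {
    cs <- utils::read.delim(chrom_sizes, header = TRUE, comment.char = "#")
    chrom_sizes <- stats::setNames(as.numeric(cs$length), cs$chrom)
  }
  if (is.null(chrom_sizes)) {
    ends <- tapply(GenomicRanges::end(genes),
                   as.character(GenomicRanges::seqnames(genes)), max)
    chrom_sizes <- stats::setNames(as.numeric(ends) + window, names(ends))
  }

  promoters <- stage("annotations", derive_promoters(genes, window, chrom_sizes))
  bodies <- gene_body_intervals(genes)
  log_msg("promoters derived: %d (%d dropped by edge clipping)",
          length(promoters), length(attr(promoters, "dropped")))

  k_set <- stage("oq_catalog", read_oq_bed(oq_kplus, "Kplus"))
  pds_set <- stage("oq_catalog", read_oq_bed(oq_pds, "PDS"))
  consensus <- stage("oq_catalog",
                     intersect_conditions(k_set, pds_set, mode = consensus_mode))
  log_msg("OQs: K+=%d, PDS=%d, consensus=%d",
          length(k_set), length(pds_set), length(consensus))

  assign_p <- stage("oq_catalog",
                    assign_contained(promoters, consensus, "promoter",
                                     strand_policy))
  assign_g <- stage("oq_catalog",
                    assign_contained(bodies, consensus, "gene", strand_policy))
  assignments <- rbind(assign_p, assign_g)

  de <- stage("de_results", read_de_table(de_table, alpha = alpha, tiers = tiers))
  part <- stage("de_results", partition_genes(de, genes$gene_id))
  log_msg("DE genes: %d of %d in universe (%d table ids unmatched)",
          length(part$groups$DE), length(part$universe), length(part$unmatched))

  classes <- if (region_class == "both") c("promoter", "gene") else region_class
  groups <- c("all", "DE", "nonDE", "DE_2FC", "nonDE_2FC")
  summaries <- do.call(rbind, lapply(classes, function(cl)
    stage("enrichment_stats",
          summarize_oq_content(assignments, part, cl, groups = groups))))

  tests <- list()
  # a sparsely populated group (e.g. no 2FC gene with a promoter OQ) is a
  # property of the data, not a pipeline failure: record it and continue
  add_test <- function(name, expr) {
    tests[[name]] <<- tryCatch(unclass(expr), error = function(e)
      list(skipped = conditionMessage(e)))
  }
  for (cl in classes) {
    add_test(paste0(cl, "_presence_DE"),
             presence_enrichment(assignments, part, cl, "DE"))
    add_test(paste0(cl, "_presence_DE_2FC"),
             presence_enrichment(assignments, part, cl, "DE_2FC"))
    add_test(paste0(cl, "_counts_DE_vs_nonDE"),
             count_comparison(assignments, part, cl, "DE", "nonDE"))
    add_test(paste0(cl, "_counts_DE_2FC_vs_nonDE_2FC"),
             count_comparison(assignments, part, cl, "DE_2FC", "nonDE_2FC"))
  }
  if ("gene" %in% classes) {
    add_test("gene_length_DE_vs_nonDE", {
      lc <- length_comparison(genes, assignments, part)
      c(lc$ranksum,
        list(mean_length_DE = lc$mean_length_a,
             mean_length_nonDE = lc$mean_length_b))
    })
  }

  tallies <- NULL
  if (!is.null(gene_lists)) {
    tallies <- do.call(rbind, lapply(names(gene_lists), function(nm)
      stage("gene_sets",
            tally_set(read_gene_list(gene_lists[[nm]]), de, set_name = nm))))
  }

  inputs <- c(annotation, oq_kplus, oq_pds, de_table)
  report <- list(
    version = as.character(utils::packageVersion("g4assoc")),
    config = list(annotation = annotation, dialect = dialect,
                  oq_kplus = oq_kplus, oq_pds = oq_pds, de_table = de_table,
                  window = window, alpha = alpha, tiers = tiers,
                  chroms = chroms, strand_policy = strand_policy,
                  consensus_mode = consensus_mode,
                  region_class = region_class),
    input_checksums = unname_md5(inputs),
    stages = list(
      n_genes = length(genes),
      n_promoters = length(promoters),
      n_promoters_dropped = length(attr(promoters, "dropped")),
      n_oq_kplus = length(k_set),
      n_oq_pds = length(pds_set),
      n_consensus_oqs = length(consensus),
      n_de_table_rows = nrow(de)
    ),
    partition_sizes = lapply(part$groups, length),
    summaries = summaries,
    tests = tests
  )
  if (!is.null(tallies)) report$gene_set_tallies <- tallies

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(assignments, file.path(outdir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summaries, file.path(outdir, "summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pt <- do.call(rbind, lapply(names(part$groups), function(g)
      if (length(part$groups[[g]]))
        data.frame(gene_id = part$groups[[g]], group = g)))
    utils::write.table(pt, file.path(outdir, "partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_oq_bed(consensus, file.path(outdir, "consensus.bed"))
    write_regions_bed(promoters, file.path(outdir, "promoters.bed"))
    log_msg("report written to %s", outdir)
  }
  invisible(report)
}
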