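#' Read an observed-quadruplex BED file
#'
#' Reads a BED3+ interval set from one G4-Seq stabilizer condition. BED
#' coordinates are 0-based half-open and are converted to the in-memory
#' 1-based closed representation. Records with start >= end or missing
#' columns are rejected with their line numbers.
#'
#' @param path Path to the BED file.
#' @param source Condition label, `"Kplus"` or `"PDS"` (or `"consensus"`
#'   when re-reading a written catalog).
#' @return `GRanges` with metadata column `source`, unstranded.
#' @export
read_oq_bed <- function(path, source = c("Kplus", "PDS", "consensus")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop_g4("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) == 0L) stop_g4("no interval records in ", path)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop_g4("BED record with fewer than 3 columns at line(s): ",
            paste(utils::head(lineno[nf < 3L], 5), collapse = ", "))
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end)
  if (any(bad))
    stop_g4("non-numeric BED coordinates at line(s): ",
            paste(utils::head(lineno[bad], 5), collapse = ", "))
  bad <- start0 < 0 | end <= start0
  if (any(bad))
    stop_g4("invalid interval (start >= end or negative) at line(s): ",
            paste(utils::head(lineno[bad], 5), collapse = ", "))
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end),
    strand = "*",
    source = source
  )
}

#' Build the consensus OQ catalog from two stabilizer conditions
#'
#' G4-Seq detects observed quadruplexes under two stabilizing conditions
#' (K+ ion and pyridostatin); the consensus catalog keeps only structure
#' calls supported by both. In the default `"intersect"` mode the consensus
#' is the coordinate intersection of every overlapping K+/PDS pair, with
#' overlapping or bookended results merged and sorted. The alternative
#' `"kplus-anchored"` mode keeps the full K+ interval whenever any PDS
#' overlap exists (this changes downstream OQ counts).
#'
#' @param k_set,pds_set `GRanges` from [read_oq_bed()] for the two
#'   conditions.
#' @param mode `"intersect"` (default) or `"kplus-anchored"`.
#' @return Sorted `GRanges` with `source = "consensus"`.
#' @export
intersect_conditions <- function(k_set, pds_set,
                                 mode = c("intersect", "kplus-anchored")) {
  mode <- match.arg(mode)
  if (length(k_set) == 0L || length(pds_set) == 0L)
    stop_g4("both condition sets must be non-empty")
  shared <- intersect(GenomeInfoDb::seqlevelsInUse(k_set),
                      GenomeInfoDb::seqlevelsInUse(pds_set))
  if (length(shared) == 0L)
    stop_g4("the two condition sets share no chromosome names; ",
            "check naming conventions (e.g. 'chr' prefix)")
  if (mode == "intersect") {
    cons <- GenomicRanges::intersect(GenomicRanges::granges(k_set),
                                     GenomicRanges::granges(pds_set),
                                     ignore.strand = TRUE)
  } else {
    cons <- IRanges::subsetByOverlaps(GenomicRanges::granges(k_set),
                                      pds_set, ignore.strand = TRUE)
  }
  # fix seqlevel order so output ordering is by chromosome name, not by
  # order of first appearance in the inputs
  GenomeInfoDb::seqlevels(cons) <- sort(GenomeInfoDb::seqlevels(cons))
  cons <- GenomicRanges::sort(cons, ignore.strand = TRUE)
  cons$source <- rep("consensus", length(cons))
  cons
}

#' Count OQs strictly contained in each region
#'
#' Assigns observed quadruplexes to regions by strict containment: an OQ is
#' counted for a region only if its coordinates lie entirely within the
#' region on the same chromosome. An OQ contained in several (overlapping)
#' regions increments each of them. Strand is ignored unless
#' `strand_policy = "match"`. Lookup uses the interval-index overlap engine;
#' an all-pairs scan is equivalent and serves as the test oracle.
#'
#' @param regions `GRanges` with metadata column `gene_id` (promoters or
#'   gene bodies), unique ids within the class.
#' @param oqs `GRanges` of OQ intervals.
#' @param region_class Label recorded in the output, e.g. `"promoter"` or
#'   `"gene"`.
#' @param strand_policy `"ignore"` (default) or `"match"`.
#' @return `data.frame` with columns `region_id`, `region_class`,
#'   `oq_count`; every input region appears exactly once, in input order.
#' @export
assign_contained <- function(regions, oqs, region_class = "promoter",
                             strand_policy = c("ignore", "match")) {
  strand_policy <- match.arg(strand_policy)
  if (anyDuplicated(regions$gene_id))
    stop_g4("region ids must be unique within a region class")
  if (length(oqs) == 0L) {
    counts <- integer(length(regions))
  } else {
    hits <- GenomicRanges::findOverlaps(
      oqs, regions, type = "within",
      ignore.strand = (strand_policy == "ignore"))
    counts <- tabulate(S4Vectors::subjectHits(hits), nbins = length(regions))
  }
  data.frame(
    region_id = regions$gene_id,
    region_class = region_class,
    oq_count = counts,
    stringsAsFactors = FALSE
  )
}

#' Write an OQ catalog as BED3
#'
#' @param oqs `GRanges` of OQ intervals.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_oq_bed <- function(oqs, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(oqs)),
    start = GenomicRanges::start(oqs) - 1L,
    end = GenomicRanges::end(oqs)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
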