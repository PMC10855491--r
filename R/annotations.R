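#' Read a gene-level annotation
#'
#' Reads gene records from a GTF, GFF3, or simple TSV annotation and returns
#' them as a [GenomicRanges::GRanges] with one range per gene. GTF/GFF
#' coordinates (1-based, closed) are used as-is in the returned `GRanges`;
#' the TSV dialect carries 0-based half-open coordinates (columns
#' `gene_id, chrom, start0, end, strand, biotype`) which are shifted to
#' 1-based on import. Biotypes are collapsed to the two-way
#' `protein_coding` / `non_coding` classification.
#'
#' @param path Path to the annotation file.
#' @param dialect One of `"gtf"`, `"gff3"`, `"tsv"`.
#' @param chrom_filter Optional character vector of allowed chromosome names
#'   (applied after any `strip_chr` normalization). Genes on other sequences
#'   are dropped.
#' @param id_attr Attribute key holding the gene identifier for GTF/GFF
#'   input; defaults to `"gene_id"` (GTF) or `"ID"` (GFF3).
#' @param biotype_attr Attribute key holding the biotype for GTF/GFF input;
#'   if `NULL`, the first of `gene_biotype`, `gene_type`, `biotype` present
#'   is used.
#' @param strip_chr If `TRUE`, a leading `"chr"` prefix is removed from
#'   chromosome names so annotation and BED resources with different naming
#'   conventions can be mixed.
#' @return A `GRanges` with metadata columns `gene_id` and `biotype`
#'   (`protein_coding`/`non_coding`), strand `+` or `-`, in file order.
#' @export
read_gene_annotation <- function(path, dialect = c("tsv", "gtf", "gff3"),
                                 chrom_filter = NULL, id_attr = NULL,
                                 biotype_attr = NULL, strip_chr = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_g4("annotation file not found: ", path)
  if (dialect == "tsv") {
    genes <- read_gene_tsv(path)
  } else {
    genes <- read_gene_gff(path, dialect, id_attr, biotype_attr)
  }
  if (strip_chr) {
    GenomeInfoDb::seqlevels(genes) <- strip_chr_prefix(GenomeInfoDb::seqlevels(genes))
  }
  if (!is.null(chrom_filter)) {
    genes <- genes[as.character(GenomicRanges::seqnames(genes)) %in% chrom_filter]
    genes <- GenomeInfoDb::keepSeqlevels(genes, GenomeInfoDb::seqlevelsInUse(genes))
  }
  if (length(genes) == 0L)
    stop_g4("no gene records remain after chromosome filtering")
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup))
    stop_g4("duplicate gene_id in annotation: ", paste(utils::head(dup, 5), collapse = ", "))
  if (!all(as.character(GenomicRanges::strand(genes)) %in% c("+", "-")))
    stop_g4("gene records must have strand '+' or '-'")
  genes
}

read_gene_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start0", "end", "strand", "biotype")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_g4("annotation TSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(df$start0 >= 0 & df$end > df$start0))
  if (length(bad))
    stop_g4("invalid gene coordinates at data row(s): ",
            paste(utils::head(bad, 5), collapse = ", "))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end),
    strand = df$strand,
    gene_id = df$gene_id,
    biotype = normalize_biotype(df$biotype)
  )
}

read_gene_gff <- function(path, dialect, id_attr, biotype_attr) {
  fmt <- if (dialect == "gtf") "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) stop_g4("no gene-level features found in ", path)
  id_attr <- id_attr %||% if (dialect == "gtf") "gene_id" else "ID"
  ids <- S4Vectors::mcols(gr)[[id_attr]]
  if (is.null(ids))
    stop_g4("gene identifier attribute '", id_attr, "' not present in ", path)
  if (is.null(biotype_attr)) {
    cand <- intersect(c("gene_biotype", "gene_type", "biotype"),
                      names(S4Vectors::mcols(gr)))
    if (length(cand) == 0L)
      stop_g4("no biotype attribute (gene_biotype/gene_type/biotype) in ", path,
              "; supply 'biotype_attr'")
    biotype_attr <- cand[1L]
  }
  bt <- S4Vectors::mcols(gr)[[biotype_attr]]
  if (is.null(bt)) stop_g4("biotype attribute '", biotype_attr, "' not present")
  out <- GenomicRanges::granges(gr)
  out$gene_id <- as.character(ids)
  out$biotype <- normalize_biotype(bt)
  out
}

normalize_biotype <- function(x) {
  ifelse(as.character(x) == "protein_coding", "protein_coding", "non_coding")
}

#' Derive strand-aware promoter windows
#'
#' For each gene, the promoter is the fixed-width window directly upstream of
#' the transcription start site, taken as the 5' end of the annotated gene
#' span: for a `+` strand gene the `window` bases before its start, for a
#' `-` strand gene the `window` bases after its end. Promoters running past
#' a chromosome edge are clipped and flagged; promoters clipped to zero
#' length are dropped and reported via the `"dropped"` attribute.
#'
#' @param genes `GRanges` of genes as returned by [read_gene_annotation()].
#' @param window Upstream window width in bp (default 1000).
#' @param chrom_sizes Named numeric vector of chromosome lengths; every gene
#'   chromosome must be present.
#' @return `GRanges` with metadata columns `gene_id`, `window`, `clipped`;
#'   attribute `"dropped"` lists gene_ids whose promoter clipped to nothing.
#' @export
derive_promoters <- function(genes, window = 1000, chrom_sizes) {
  check_scalar_number(window, "window", lower = 1)
  chroms <- as.character(GenomicRanges::seqnames(genes))
  absent <- setdiff(unique(chroms), names(chrom_sizes))
  if (length(absent))
    stop_g4("chromosome(s) missing from chrom_sizes: ",
            paste(absent, collapse = ", "))
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  s <- ifelse(plus,
              GenomicRanges::start(genes) - window,
              GenomicRanges::end(genes) + 1L)
  e <- s + window - 1L
  len <- unname(chrom_sizes[chroms])
  cs <- pmax(s, 1)
  ce <- pmin(e, len)
  keep <- cs <= ce
  prom <- GenomicRanges::GRanges(
    seqnames = chroms[keep],
    ranges = IRanges::IRanges(start = cs[keep], end = ce[keep]),
    strand = GenomicRanges::strand(genes)[keep],
    gene_id = genes$gene_id[keep],
    window = rep(window, sum(keep)),
    clipped = (cs[keep] != s[keep]) | (ce[keep] != e[keep])
  )
  attr(prom, "dropped") <- genes$gene_id[!keep]
  prom
}

#' Extract gene-body intervals
#'
#' Identity extraction of each gene's full annotated span, keyed by gene_id.
#' Order is preserved.
#'
#' @param genes `GRanges` of genes.
#' @return `GRanges` with metadata column `gene_id`.
#' @export
gene_body_intervals <- function(genes) {
  out <- GenomicRanges::granges(genes)
  out$gene_id <- genes$gene_id
  out
}

#' Write regions as BED6
#'
#' Writes a region set (promoters or gene bodies) as BED6 with
#' `name = gene_id` and `score = 0`. BED coordinates are 0-based half-open;
#' the conversion from the in-memory 1-based representation happens here.
#'
#' @param regions `GRanges` with a `gene_id` metadata column.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    name = regions$gene_id,
    score = 0L,
    strand = as.character(GenomicRanges::strand(regions))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
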