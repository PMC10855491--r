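#' Read a differential-expression results table
#'
#' Ingests a DESeq2-shaped TSV of per-gene differential-expression results
#' and stratifies genes by significance and fold-change tier. A gene is
#' called differentially expressed (DE) when its adjusted p-value is present
#' and below `alpha`; genes with missing `padj` (e.g. removed by independent
#' filtering) are retained as non-DE so the analysis universe stays the full
#' annotation. Fold-change tiers are inclusive: tier k is passed when the
#' gene is DE and `|log2fc| >= log2(k)`.
#'
#' @param path Path to the TSV.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param tiers Fold-change tiers (default `c(2, 5, 10)`).
#' @param columns Named character vector mapping the required fields
#'   `gene_id`, `log2fc`, `pvalue`, `padj` to the file's column names.
#' @return `data.frame` with the input fields plus `is_de`, `direction`
#'   (`up`/`down`/`none`) and one logical `tier_<k>` column per tier.
#' @export
read_de_table <- function(path, alpha = 0.05, tiers = c(2, 5, 10),
                          columns = c(gene_id = "gene_id", log2fc = "log2fc",
                                      pvalue = "pvalue", padj = "padj")) {
  if (!file.exists(path)) stop_g4("DE table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  miss <- setdiff(unname(columns), names(df))
  if (length(miss))
    stop_g4("DE table missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    gene_id = as.character(df[[columns[["gene_id"]]]]),
    log2fc = as.numeric(df[[columns[["log2fc"]]]]),
    pvalue = as.numeric(df[[columns[["pvalue"]]]]),
    padj = as.numeric(df[[columns[["padj"]]]]),
    stringsAsFactors = FALSE
  )
  dup <- unique(out$gene_id[duplicated(out$gene_id)])
  if (length(dup))
    stop_g4("duplicate gene_id in DE table: ",
            paste(utils::head(dup, 5), collapse = ", "))
  stratify_de(out, alpha = alpha, tiers = tiers)
}

#' Stratify an in-memory DE table
#'
#' Same stratification as [read_de_table()] applied to a `data.frame` that
#' already has columns `gene_id`, `log2fc`, `pvalue`, `padj`.
#'
#' @inheritParams read_de_table
#' @param df DE results `data.frame`.
#' @return See [read_de_table()].
#' @export
stratify_de <- function(df, alpha = 0.05, tiers = c(2, 5, 10)) {
  tiers <- sort(tiers)
  df$is_de <- !is.na(df$padj) & df$padj < alpha
  df$direction <- ifelse(!df$is_de, "none", ifelse(df$log2fc > 0, "up", "down"))
  for (k in tiers)
    df[[paste0("tier_", k)]] <- df$is_de & abs(df$log2fc) >= log2(k)
  attr(df, "alpha") <- alpha
  attr(df, "tiers") <- tiers
  df
}

#' Partition genes into DE-analysis groups
#'
#' Builds the gene groups used by the enrichment tests: `DE` and its
#' annotation complement `nonDE`, the 2-fold subset `DE_2FC` and complement
#' `nonDE_2FC`, and the direction groups `up`/`down`. The non-DE background
#' is defined as every annotated gene not called DE, including genes absent
#' from (or untested in) the DE table. DE-table genes missing from the
#' universe are excluded and reported in the `unmatched` field.
#'
#' @param records Stratified DE `data.frame` from [read_de_table()].
#' @param universe Character vector of all annotated gene ids.
#' @return Object of class `g4_partition`: a list with `groups` (named list
#'   of gene-id vectors), `universe`, `unmatched`, `alpha`.
#' @export
partition_genes <- function(records, universe) {
  if (length(universe) == 0L) stop_g4("gene universe is empty")
  universe <- unique(as.character(universe))
  unmatched <- setdiff(records$gene_id, universe)
  rec <- records[records$gene_id %in% universe, , drop = FALSE]
  de <- rec$gene_id[rec$is_de]
  tier2col <- grep("^tier_", names(rec), value = TRUE)[1]
  de2 <- rec$gene_id[rec[[tier2col]]]
  groups <- list(
    DE = de,
    nonDE = setdiff(universe, de),
    DE_2FC = de2,
    nonDE_2FC = setdiff(universe, de2),
    up = rec$gene_id[rec$direction == "up"],
    down = rec$gene_id[rec$direction == "down"]
  )
  structure(
    list(groups = groups, universe = universe, unmatched = unmatched,
         alpha = attr(records, "alpha") %||% NA_real_),
    class = "g4_partition"
  )
}

#' @export
print.g4_partition <- function(x, ...) {
  cat("g4_partition:", length(x$universe), "genes in universe\n")
  for (g in names(x$groups))
    cat(sprintf("  %-10s %d\n", g, length(x$groups[[g]])))
  if (length(x$unmatched))
    cat("  unmatched DE-table ids:", length(x$unmatched), "\n")
  invisible(x)
}

#' Tier counts by direction
#'
#' Counts DE genes passing each fold-change tier, split by direction, as a
#' compact summary of the stratification.
#'
#' @param records Stratified DE `data.frame`.
#' @return `data.frame` with columns `tier`, `n_up`, `n_down`.
#' @export
tier_counts <- function(records) {
  tiers <- attr(records, "tiers")
  do.call(rbind, lapply(tiers, function(k) {
    pass <- records[[paste0("tier_", k)]]
    data.frame(tier = k,
               n_up = sum(pass & records$direction == "up"),
               n_down = sum(pass & records$direction == "down"))
  }))
}
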