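#' Read a gene list (one id per line)
#'
#' @param path File path; lines starting with `#` and blank lines ignored.
#' @return Character vector of gene ids (duplicates retained; [tally_set()]
#'   de-duplicates).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Tally differentially expressed genes in a gene set
#'
#' Counts how many members of a user-supplied gene list (e.g. transcription
#' factors, oncogenes, G4 helicases) are differentially expressed, split by
#' direction and by the first fold-change tier (2-fold). Reconciliation is
#' exact-match on gene_id after de-duplication, optionally through an alias
#' map; unmatched ids are reported, and a set that reconciles to nothing is
#' an error.
#'
#' @param set_genes Character vector of gene ids in the set.
#' @param records Stratified DE `data.frame` from [read_de_table()].
#' @param set_name Label stored in the tally.
#' @param alias_map Optional named character vector mapping set ids to
#'   annotation gene ids.
#' @return `data.frame` with one row: `set_name`, `n_set`, `n_matched`,
#'   `n_de_in_set`, `n_up`, `n_down`, `n_up_tier2`, `n_down_tier2`;
#'   attribute `"unmatched"` holds unreconciled ids.
#' @export
tally_set <- function(set_genes, records, set_name = "gene_set",
                      alias_map = NULL) {
  ids <- unique(as.character(set_genes))
  if (!is.null(alias_map)) {
    hit <- ids %in% names(alias_map)
    ids[hit] <- unname(alias_map[ids[hit]])
    ids <- unique(ids)
  }
  matched <- intersect(ids, records$gene_id)
  if (length(matched) == 0L)
    stop_g4("gene set '", set_name, "' is empty after id reconciliation")
  rec <- records[records$gene_id %in% matched, , drop = FALSE]
  tier2col <- grep("^tier_", names(rec), value = TRUE)[1]
  up <- rec$direction == "up"
  down <- rec$direction == "down"
  out <- data.frame(
    set_name = set_name,
    n_set = length(ids),
    n_matched = length(matched),
    n_de_in_set = sum(rec$is_de),
    n_up = sum(up),
    n_down = sum(down),
    n_up_tier2 = sum(up & rec[[tier2col]]),
    n_down_tier2 = sum(down & rec[[tier2col]]),
    stringsAsFactors = FALSE
  )
  attr(out, "unmatched") <- setdiff(ids, matched)
  out
}
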