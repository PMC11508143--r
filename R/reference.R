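#' Published module and key-gene tallies for 'Jao Khao' rice under salt
#'
#' The module bookkeeping reported for the two-state co-expression analysis
#' of the salt-tolerant Thai rice variety 'Jao Khao' (36 leaf transcriptome
#' libraries, 1,950 high-variance genes): per-module gene totals and the
#' key hub genes identified by degree-centrality change between the normal
#' and saline state networks. Used as a worked bookkeeping example; the raw
#' sequencing data behind it are not publicly deposited.
#'
#' @return data.frame: module, total_genes, key_genes (one row per module).
#' @export
reference_module_table <- function() {
  data.frame(
    module = c("grey", "green", "turquoise", "yellow", "red", "blue", "brown"),
    total_genes = c(362L, 59L, 610L, 113L, 48L, 567L, 191L),
    key_genes = c(14L, 5L, 59L, 13L, 1L, 18L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Summarize a module/key-gene bookkeeping table
#'
#' Adds per-module key-gene percentages and the overall totals row:
#' total genes, total key genes, and the overall key-gene percentage
#' (rounded to one decimal).
#'
#' @param tab data.frame with columns module, total_genes, key_genes.
#' @return List: `per_module` (with a percentage column), `total_genes`,
#'   `total_key_genes`, `overall_percentage`.
#' @export
summarize_module_table <- function(tab) {
  stopifnot(all(c("module", "total_genes", "key_genes") %in% colnames(tab)))
  if (any(tab$key_genes > tab$total_genes))
    stop("a module cannot contain more key genes than genes")
  per <- tab
  per$percentage <- round(100 * per$key_genes / per$total_genes, 1)
  list(per_module = per,
       total_genes = sum(tab$total_genes),
       total_key_genes = sum(tab$key_genes),
       overall_percentage = round(100 * sum(tab$key_genes) / sum(tab$total_genes), 1))
}
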