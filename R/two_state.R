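#' Normalize centralities to their within-network maximum
#'
#' Divides each measure (DG, BW, CN, CC) by its maximum over the network so
#' that networks of different size and density become comparable; an
#' all-zero measure is left as zeros.
#'
#' @param tab Centrality table from [node_centralities()].
#' @return The table with each measure rescaled to `[0, 1]`.
#' @export
normalize_centrality <- function(tab) {
  if (!nrow(tab)) stop("cannot normalize an empty centrality table")
  for (m in c("DG", "BW", "CN", "CC")) {
    mx <- max(tab[[m]])
    if (mx > 0) tab[[m]] <- tab[[m]] / mx
  }
  tab
}

#' Per-gene centrality change between the normal and stress states
#'
#' Takes max-normalized centrality tables of the two state networks, forms
#' the union of their genes (a gene absent from a network scores zero
#' there), and reports the change in percentage points
#' `delta = (c_stress - c_normal) * 100` for each of DG, BW, CN, CC.
#'
#' @param normal,saline Normalized centrality tables
#'   ([normalize_centrality()]) of the normal-state and stress-state
#'   networks.
#' @return data.frame: gene_id, in_normal, in_saline, dDG, dBW, dCN, dCC
#'   (changes in `[-100, 100]`).
#' @export
centrality_change <- function(normal, saline) {
  genes <- union(normal$gene_id, saline$gene_id)
  measures <- c("DG", "BW", "CN", "CC")
  get_side <- function(tab) {
    m <- matrix(0, nrow = length(genes), ncol = length(measures),
                dimnames = list(genes, measures))
    idx <- match(tab$gene_id, genes)
    for (ms in measures) m[idx, ms] <- tab[[ms]]
    m
  }
  cn <- get_side(normal)
  cs <- get_side(saline)
  delta <- (cs - cn) * 100
  data.frame(gene_id = genes,
             in_normal = genes %in% normal$gene_id,
             in_saline = genes %in% saline$gene_id,
             dDG = delta[, "DG"], dBW = delta[, "BW"],
             dCN = delta[, "CN"], dCC = delta[, "CC"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Identify key hub genes from centrality change
#'
#' A gene is a key hub gene when (a) it is present in the global network and
#' (b) its degree-centrality change strictly surpasses the threshold. The
#' same threshold applied to the other three measures yields the number of
#' measures passed (1-4; degree always counts by construction).
#'
#' @param changes Change table from [centrality_change()].
#' @param global_nodes Gene ids present in the global network.
#' @param modules Named module-label vector ([cluster_modules()]); genes
#'   without a label are reported as "grey".
#' @param threshold Percentage-point change required, in `(0, 100]`.
#' @return data.frame: gene_id, module, n_measures_passed, dDG, dBW, dCN,
#'   dCC, sorted by decreasing dDG.
#' @export
identify_key_genes <- function(changes, global_nodes, modules = NULL,
                               threshold = 80) {
  if (threshold <= 0 || threshold > 100) stop("threshold must lie in (0, 100]")
  key <- changes[changes$gene_id %in% global_nodes & changes$dDG > threshold, ,
                 drop = FALSE]
  passed <- rowSums(cbind(key$dDG, key$dBW, key$dCN, key$dCC) > threshold)
  mod <- rep("grey", nrow(key))
  if (!is.null(modules)) {
    hit <- match(key$gene_id, names(modules))
    mod[!is.na(hit)] <- modules[hit[!is.na(hit)]]
  }
  out <- data.frame(gene_id = key$gene_id, module = mod,
                    n_measures_passed = as.integer(passed),
                    dDG = key$dDG, dBW = key$dBW, dCN = key$dCN, dCC = key$dCC,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$dDG), , drop = FALSE]
}
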