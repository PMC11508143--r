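#' Read gene-set annotations from a GMT file
#'
#' Tab-delimited, one term per line: `term_id<TAB>term_name<TAB>gene...`.
#' If the term name carries a leading namespace tag such as `BP|...`,
#' `CC|...`, `MF|...` or `pathway|...` it is split off into the namespace
#' column.
#'
#' @param path Path to a GMT file.
#' @return List of two elements: `terms`, a data.frame (term_id, term_name,
#'   namespace); and `sets`, a named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has no member genes")
  term_id <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(term_id))
    stop("duplicated term id(s): ",
         paste(unique(term_id[duplicated(term_id)]), collapse = ", "))
  name_raw <- vapply(fields, `[[`, "", 2L)
  has_ns <- grepl("^(BP|CC|MF|pathway)\\|", name_raw)
  namespace <- ifelse(has_ns, sub("\\|.*$", "", name_raw), NA_character_)
  term_name <- ifelse(has_ns, sub("^[^|]*\\|", "", name_raw), name_raw)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- term_id
  list(terms = data.frame(term_id = term_id, term_name = term_name,
                          namespace = namespace, stringsAsFactors = FALSE),
       sets = sets)
}

#' Hypergeometric over-representation test of a gene set
#'
#' For each annotation term, tests whether the module's overlap with the
#' term is larger than expected when drawing `n` genes from a universe of
#' `N` containing `K` term members: upper-tail `P(X >= kx)` of the
#' hypergeometric distribution, BH-adjusted across terms.
#'
#' @param module_genes Character vector of gene ids (the module).
#' @param annotations Annotation map from [read_gmt()].
#' @param universe Background gene ids; module genes outside the universe
#'   are dropped, term memberships are intersected with it.
#' @return data.frame (term_id, term_name, namespace, kx, n, K, N, p, padj)
#'   sorted by adjusted p. Terms with no member in the universe are omitted.
#' @export
hypergeom_enrich <- function(module_genes, annotations, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  module_genes <- intersect(unique(module_genes), universe)
  n <- length(module_genes)
  N <- length(universe)
  sets <- lapply(annotations$sets, intersect, universe)
  keep <- lengths(sets) > 0L
  sets <- sets[keep]
  terms <- annotations$terms[keep, , drop = FALSE]
  K <- lengths(sets)
  kx <- vapply(sets, function(s) length(intersect(s, module_genes)), 1L)
  p <- stats::phyper(kx - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms$term_id, term_name = terms$term_name,
                    namespace = terms$namespace,
                    kx = as.integer(kx), n = n, K = as.integer(K), N = N,
                    p = pmin(p, 1), padj = bh_adjust(pmin(p, 1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$padj, out$p), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up with monotonicity enforcement, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
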