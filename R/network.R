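#' Threshold a TOM matrix into an undirected weighted graph
#'
#' Keeps every gene pair whose topological overlap is at least `min_weight`;
#' genes left without any edge are excluded from the graph, so every node
#' has at least one incident edge.
#'
#' @param tom TOM similarity matrix.
#' @param min_weight Lowest edge weight kept, in `(0, 1]`.
#' @return An [igraph::graph] with vertex names and a `weight` edge
#'   attribute; possibly the empty graph.
#' @export
build_network <- function(tom, min_weight = 0.1) {
  if (min_weight <= 0 || min_weight > 1) stop("min_weight must lie in (0, 1]")
  idx <- which(upper.tri(tom) & tom >= min_weight, arr.ind = TRUE)
  edges <- data.frame(source = rownames(tom)[idx[, 1L]],
                      target = colnames(tom)[idx[, 2L]],
                      weight = tom[idx],
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Write a network as a tab-delimited edge list
#'
#' Format: `source<TAB>target<TAB>weight` with a header row (importable into
#' Cytoscape and readable back with [read_edge_list()]).
#'
#' @param g igraph network with a `weight` edge attribute.
#' @param path Output path.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  colnames(el)[1:2] <- c("source", "target")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @return `read_edge_list` returns the igraph network.
#' @export
read_edge_list <- function(path) {
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE)
}

#' Whole-network summary statistics
#'
#' Node and edge counts, average degree `2E/N`, median degree, the diameter
#' of the largest connected component (unweighted shortest paths), and the
#' average local clustering coefficient (nodes with fewer than two
#' neighbors count as zero).
#'
#' @param g igraph network.
#' @return One-row data.frame: n_nodes, n_edges, average_degree,
#'   median_degree, diameter, average_clustering, empty.
#' @export
network_properties <- function(g) {
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0L) {
    return(data.frame(n_nodes = 0L, n_edges = 0L, average_degree = 0,
                      median_degree = 0, diameter = 0, average_clustering = 0,
                      empty = TRUE))
  }
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  diam <- igraph::diameter(sub, weights = NA)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  data.frame(n_nodes = n, n_edges = e, average_degree = 2 * e / n,
             median_degree = stats::median(deg), diameter = diam,
             average_clustering = mean(cc), empty = FALSE)
}

#' Node centralities: degree, betweenness, closeness, clustering coefficient
#'
#' Shortest-path measures treat edges as unweighted and are computed within
#' each connected component, normalized by component size: closeness is
#' `(n_c - 1) / sum of distances`, betweenness is the shortest-path fraction
#' sum divided by `(n_c - 1)(n_c - 2) / 2`. The clustering coefficient is
#' the triangle fraction among a node's neighbors (zero when degree < 2).
#' All four measures lie in `[0, 1]` except degree, which is the raw
#' incident-edge count.
#'
#' @param g igraph network.
#' @return data.frame: gene_id, DG, BW, CN, CC.
#' @export
node_centralities <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(data.frame(gene_id = character(), DG = integer(), BW = numeric(),
                      CN = numeric(), CC = numeric(), stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  bw <- numeric(n)
  cn <- numeric(n)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    nc <- length(vids)
    sub <- igraph::induced_subgraph(g, vids)
    if (nc >= 2L) {
      d <- igraph::distances(sub, weights = NA)
      cn[vids] <- (nc - 1) / rowSums(d)
    } else {
      cn[vids] <- 0
    }
    if (nc >= 3L) {
      bw_raw <- igraph::betweenness(sub, weights = NA, directed = FALSE)
      bw[vids] <- bw_raw / ((nc - 1) * (nc - 2) / 2)
    }
  }
  data.frame(gene_id = igraph::V(g)$name, DG = as.integer(deg), BW = bw,
             CN = cn, CC = cc, row.names = NULL, stringsAsFactors = FALSE)
}
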