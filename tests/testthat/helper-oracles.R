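# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops / direct definitions, not the code
# paths under test.

# Pearson correlation by the direct two-pass covariance/sd formula.
bf_correlation <- function(x) {
  n <- nrow(x)
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xi <- x[i, ] - mean(x[i, ])
    xj <- x[j, ] - mean(x[j, ])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  dimnames(out) <- list(rownames(x), rownames(x))
  out
}

# Topological overlap by the definitional triple loop.
bf_tom <- function(a) {
  n <- nrow(a)
  t_mat <- matrix(0, n, n, dimnames = dimnames(a))
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { t_mat[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    t_mat[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  t_mat
}

# Random symmetric adjacency with unit diagonal, entries in [0, 1].
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# Random undirected igraph on n nodes with edge probability p (named
# vertices, unit weights); may be disconnected or have isolated vertices
# removed, as build_network would.
random_graph <- function(n, p = 0.15) {
  adj <- matrix(runif(n * n) < p, n, n)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  if (!nrow(idx)) return(igraph::make_empty_graph(directed = FALSE))
  edges <- data.frame(from = paste0("n", idx[, 1]), to = paste0("n", idx[, 2]),
                      weight = 1)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

# All-pairs BFS distances and shortest-path counts from one source.
bf_bfs <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in which(adj[v, ])) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# Degree, betweenness, closeness and clustering coefficient from first
# principles: all-pairs BFS with path counting, pair-dependency summation,
# and triangle counting, normalized per connected component.
bf_centralities <- function(g) {
  n <- igraph::vcount(g)
  names_v <- igraph::V(g)$name
  adj <- matrix(FALSE, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(el))) {
    adj[el[r, 1], el[r, 2]] <- TRUE
    adj[el[r, 2], el[r, 1]] <- TRUE
  }
  deg <- rowSums(adj)
  bfs <- lapply(seq_len(n), function(s) bf_bfs(adj, s))
  dist <- do.call(rbind, lapply(bfs, `[[`, "dist"))
  comp <- ifelse(is.infinite(dist), 0L, 1L)      # reachability matrix
  bw <- numeric(n)
  cn <- numeric(n)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(dist[v, ]))
    nc <- length(reach)
    if (nc >= 2L) cn[v] <- (nc - 1) / sum(dist[v, setdiff(reach, v)])
    if (nc >= 3L) {
      others <- setdiff(reach, v)
      acc <- 0
      for (ii in seq_along(others)) for (jj in seq_len(ii - 1L)) {
        s <- others[ii]; t <- others[jj]
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          acc <- acc + bfs[[s]]$sigma[v] * bfs[[v]]$sigma[t] / bfs[[s]]$sigma[t]
        }
      }
      bw[v] <- acc / ((nc - 1) * (nc - 2) / 2)
    }
    if (deg[v] >= 2L) {
      nb <- which(adj[v, ])
      tri <- 0
      for (ii in seq_along(nb)) for (jj in seq_len(ii - 1L))
        if (adj[nb[ii], nb[jj]]) tri <- tri + 1
      cc[v] <- 2 * tri / (deg[v] * (deg[v] - 1))
    }
  }
  data.frame(gene_id = names_v, DG = as.integer(deg), BW = bw, CN = cn,
             CC = cc, stringsAsFactors = FALSE)
}

# A TOM-like symmetric weight matrix from an explicit edge list, for
# constructing small graphs through build_network.
tom_from_edges <- function(nodes, edges, weight = 0.5) {
  n <- length(nodes)
  m <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    w <- if (ncol(edges) >= 3) as.numeric(edges[r, 3]) else weight
    m[edges[r, 1], edges[r, 2]] <- w
    m[edges[r, 2], edges[r, 1]] <- w
  }
  diag(m) <- 1
  m
}

# Small simulation config used by pipeline-level tests (three modules, one
# stress-specific, scaled down to run fast).
small_sim_config <- function(seed) {
  sim_config(n_genes = 300, n_modules = 3, genes_per_module = 60,
             stress_modules = 3, n_hubs = 6, seed = seed)
}
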