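#' Gene-gene Pearson correlation matrix
#'
#' @param x Expression matrix (genes x samples), at least three samples,
#'   every gene with positive variance.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_correlation <- function(x) {
  if (ncol(x) < 3L) stop("need at least three samples for correlation")
  v <- row_variances(x)
  if (any(v == 0))
    stop("zero-variance gene(s) cannot be correlated: ",
         paste(utils::head(rownames(x)[v == 0], 5L), collapse = ", "),
         " (filter before network construction)")
  r <- stats::cor(t(x))
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted adjacency `a = |r|^beta`. Raising the correlation to a
#' power suppresses weak correlations smoothly instead of hard-thresholding.
#'
#' @param r Correlation matrix.
#' @param beta Integer soft-threshold power (>= 1).
#' @return Adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
soft_adjacency <- function(r, beta) {
  if (beta < 1) stop("beta must be >= 1")
  a <- abs(r)^beta
  diag(a) <- 1
  a
}

#' Weighted connectivity of each gene
#'
#' Row sums of the adjacency excluding the self-term.
#'
#' @param a Adjacency matrix with unit diagonal.
#' @return Numeric vector `k[i] = sum_{j != i} a[i, j]`.
#' @export
connectivity <- function(a) {
  rowSums(a) - diag(a)
}

#' Scale-free topology fit of a network's connectivity distribution
#'
#' Bins the connectivities into `nbins` equal-width bins, regresses
#' `log10(mean frequency per bin)` on `log10(mean connectivity per bin)`
#' (empty bins dropped), and returns the signed fit index
#' `-sign(slope) * R^2`: close to +1 for a power-law-like (scale-free)
#' degree distribution.
#'
#' @param a Adjacency matrix with unit diagonal.
#' @param nbins Number of connectivity bins.
#' @return List with `signed_r2`, `slope`, `r2`.
#' @export
scale_free_fit <- function(a, nbins = 10) {
  k <- connectivity(a)
  if (diff(range(k)) == 0)
    stop("all connectivities are equal; scale-free fit is undefined")
  breaks <- seq(min(k), max(k), length.out = nbins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  keep <- !is.na(mean_k) & !is.na(freq) & mean_k > 0
  if (sum(keep) < 2L) stop("fewer than two occupied connectivity bins")
  lx <- log10(mean_k[keep])
  ly <- log10(freq[keep])
  slope <- stats::cov(lx, ly) / stats::var(lx)
  r2 <- stats::cor(lx, ly)^2
  list(signed_r2 = -sign(slope) * r2, slope = unname(slope), r2 = unname(r2))
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' Evaluates each candidate power and picks the smallest one whose signed
#' fit index reaches `r2_cut`. If no power reaches the cut, the power with
#' the maximal signed fit is chosen and flagged.
#'
#' @param x Filtered expression matrix (genes x samples).
#' @param powers Ascending candidate powers.
#' @param r2_cut Signed fit index required of the chosen power.
#' @param nbins Connectivity bins passed to [scale_free_fit()].
#' @return List with `power` (chosen), `reached_cut` (logical) and `report`,
#'   a data.frame with one row per power: power, signed_r2, slope, mean_k,
#'   median_k, max_k.
#' @export
pick_soft_threshold <- function(x, powers = 1:20, r2_cut = 0.9, nbins = 10) {
  if (!length(powers) || is.unsorted(powers))
    stop("powers must be a non-empty ascending vector")
  r <- pearson_correlation(x)
  rows <- lapply(powers, function(beta) {
    a <- soft_adjacency(r, beta)
    k <- connectivity(a)
    fit <- tryCatch(scale_free_fit(a, nbins = nbins),
                    error = function(e) list(signed_r2 = NA_real_, slope = NA_real_))
    data.frame(power = beta, signed_r2 = fit$signed_r2, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  report <- do.call(rbind, rows)
  ok <- which(!is.na(report$signed_r2) & report$signed_r2 >= r2_cut)
  if (length(ok)) {
    chosen <- report$power[ok[1L]]
    reached <- TRUE
  } else {
    chosen <- report$power[which.max(report$signed_r2)]
    reached <- FALSE
  }
  list(power = chosen, reached_cut = reached, report = report)
}

#' Topological overlap matrix
#'
#' Similarity combining the direct adjacency of two genes with the weight of
#' their shared neighbors:
#' `t[i,j] = (l[i,j] + a[i,j]) / (min(k[i], k[j]) + 1 - a[i,j])` where
#' `l[i,j] = sum_{u != i,j} a[i,u] a[u,j]` and `k` is the connectivity.
#' Diagonal is 1.
#'
#' @param a Adjacency matrix in `[0, 1]` with unit diagonal.
#' @return TOM similarity matrix in `[0, 1]`.
#' @export
tom_similarity <- function(a) {
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  l <- a0 %*% a0             # diag(a0)=0 removes u = i and u = j terms
  denom <- outer(k, k, pmin) + 1 - a0
  t_mat <- (l + a0) / denom
  diag(t_mat) <- 1
  t_mat[t_mat > 1] <- 1
  t_mat[t_mat < 0] <- 0
  dimnames(t_mat) <- dimnames(a)
  t_mat
}

#' Size-ranked module color labels
#'
#' The conventional color sequence used to name co-expression modules from
#' largest to smallest; "grey" is reserved for unassigned genes.
#'
#' @param n Number of labels wanted.
#' @return Character vector of n labels.
#' @export
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("module", seq.int(length(base) + 1L, n)))
}

#' Detect co-expression modules from topological overlap
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height. Clusters smaller than `min_module_size` are
#' labeled "grey" (unassigned); the rest are renamed by decreasing size to
#' the conventional color sequence (largest = "turquoise").
#'
#' @param tom TOM similarity matrix.
#' @param min_module_size Smallest cluster kept as a module.
#' @param cut_height Absolute dendrogram cut height; overrides
#'   `cut_fraction` when given.
#' @param cut_fraction Cut height as a fraction of the maximum merge
#'   height (default 0.99).
#' @return Named character vector: gene id -> module label.
#' @export
cluster_modules <- function(tom, min_module_size = 35, cut_height = NULL,
                            cut_fraction = 0.99) {
  n <- nrow(tom)
  if (min_module_size > n)
    stop("min_module_size (", min_module_size, ") exceeds gene count (", n, ")")
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  # average linkage is monotone; float noise on tied merges can still leave
  # microscopic height inversions that cutree rejects
  tree$height <- cummax(round(tree$height, 12))
  if (is.null(cut_height)) cut_height <- cut_fraction * max(tree$height)
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- rep("grey", n)
  if (length(keep)) {
    # rank kept clusters by decreasing size; ties broken by first appearance
    first_seen <- vapply(keep, function(id) which(cl == id)[1L], 1L)
    ord <- keep[order(-sizes[as.character(keep)], first_seen)]
    cols <- module_colors(length(ord))
    for (i in seq_along(ord)) labels[cl == ord[i]] <- cols[i]
  }
  names(labels) <- rownames(tom)
  labels
}

#' Module eigengene
#'
#' The first principal component of the gene-standardized module submatrix,
#' scored over samples, returned with unit Euclidean norm and oriented so
#' that its correlation with the module's mean expression profile is
#' non-negative.
#'
#' @param x Expression matrix (genes x samples).
#' @param members Gene ids belonging to the module (at least two).
#' @return Numeric vector, one value per sample.
#' @export
module_eigengene <- function(x, members) {
  missing <- setdiff(members, rownames(x))
  if (length(missing))
    stop("module member(s) not in expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (length(members) < 2L) stop("a module needs at least two genes")
  sub <- x[members, , drop = FALSE]
  std <- t(scale(t(sub)))          # standardize each gene across samples
  std[!is.finite(std)] <- 0        # constant gene contributes nothing
  sv <- svd(std, nu = 0, nv = 1)
  eig <- sv$v[, 1L]
  mean_profile <- colMeans(sub)
  ori <- stats::cor(eig, mean_profile)
  if (!is.na(ori) && ori < 0) eig <- -eig
  names(eig) <- colnames(x)
  eig
}

#' Eigengenes for every module
#'
#' @param x Expression matrix (genes x samples).
#' @param modules Named vector of module labels as from [cluster_modules()].
#' @param include_grey Also summarize the unassigned ("grey") genes.
#' @return Matrix samples x modules of eigengene values.
#' @export
module_eigengenes <- function(x, modules, include_grey = TRUE) {
  labs <- unique(modules)
  if (!include_grey) labs <- setdiff(labs, "grey")
  labs <- labs[order(match(labs, c(module_colors(50), "grey")))]
  me <- vapply(labs, function(m) module_eigengene(x, names(modules)[modules == m]),
               numeric(ncol(x)))
  rownames(me) <- colnames(x)
  me
}

#' Condition-by-time trait indicator design
#'
#' One binary column per (condition, time) group, named like `ct_0h` /
#' `ss_48h` (`ct` = control, `ss` = salt stress).
#'
#' @param sheet Sample sheet data.frame (sample_id, condition, time_h, ...).
#' @return Binary matrix samples x traits, rownames = sample ids.
#' @export
trait_design <- function(sheet) {
  tag <- ifelse(sheet$condition == "control", "ct", "ss")
  times <- sort(unique(sheet$time_h))
  cols <- as.vector(t(outer(c("ct", "ss"), times, function(a, b) paste0(a, "_", b, "h"))))
  grp <- paste0(tag, "_", sheet$time_h, "h")
  design <- vapply(cols, function(cn) as.numeric(grp == cn), numeric(nrow(sheet)))
  rownames(design) <- sheet$sample_id
  design[, colSums(design) > 0, drop = FALSE]
}

#' Two-sided p-value of a Pearson correlation
#'
#' Student-t transform `t = r sqrt((n-2)/(1-r^2))` with `n - 2` degrees of
#' freedom. Perfect correlations are reported at the machine floor instead
#' of zero.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param n Number of paired observations (>= 4 recommended).
#' @return Two-sided p-value(s) in `(0, 1]`.
#' @export
cor_pvalue <- function(r, n) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("correlations must lie in [-1, 1]")
  if (n < 3L) stop("need at least three observations")
  p <- ifelse(abs(r) >= 1, .Machine$double.xmin,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2))
  pmax(p, .Machine$double.xmin)
}

#' Module-trait relationships
#'
#' Pearson correlation of every module eigengene with every trait indicator
#' column, with the Student-t two-sided p-value. Constant indicator columns
#' give missing values.
#'
#' @param eigengenes Matrix samples x modules ([module_eigengenes()]).
#' @param design Binary trait matrix samples x traits ([trait_design()]).
#' @return Long data.frame: module, trait, r, p.
#' @export
module_trait_relationships <- function(eigengenes, design) {
  n <- nrow(eigengenes)
  if (n < 4L) stop("need at least four samples for module-trait relationships")
  if (nrow(design) != n) stop("eigengenes and design must cover the same samples")
  out <- expand.grid(module = colnames(eigengenes), trait = colnames(design),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- NA_real_
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    tr <- design[, out$trait[i]]
    if (stats::sd(tr) == 0) next   # constant indicator: correlation undefined
    r <- stats::cor(eigengenes[, out$module[i]], tr)
    out$r[i] <- r
    out$p[i] <- cor_pvalue(r, n)
  }
  out
}
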