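#' Configuration for the synthetic two-condition time-course generator
#'
#' Defaults mirror the study design the pipeline targets: 2 conditions x
#' 6 time points x 3 replicates = 36 libraries, six planted co-expression
#' modules of 80 genes among 1,000 genes, with one stress-specific module
#' whose genes are coupled only under salt, and a dozen planted hub genes
#' carrying the strongest module coupling. Several stress modules are
#' supported, but note they then share the salt-time trend (separated by
#' condition offsets) and are only approximately separable globally.
#'
#' Module activities are orthogonal polynomial time trends (unit sample
#' variance where active). Constitutive modules follow the same trend under
#' both conditions; stress-specific modules are flat (noise-only) under
#' control and strongly varying under salt, so their genes gain
#' connectivity -- not merely mean expression -- under stress.
#'
#' @param n_genes Total genes simulated.
#' @param n_modules Number of planted modules.
#' @param genes_per_module Genes per module; the remainder is uncorrelated
#'   background.
#' @param conditions Condition labels (first = unstressed reference).
#' @param time_h Sampling times in hours.
#' @param replicates Replicates per condition x time cell.
#' @param loading_mean,loading_sd Mean/sd of the gamma distribution of
#'   module loadings on the latent (natural log) scale. A right-skewed
#'   loading continuum gives the heavy-tailed connectivity distribution
#'   real co-expression networks show.
#' @param neg_loading_prob Fraction of members with anti-correlated
#'   (negative) loadings.
#' @param member_qmax Ordinary module members draw their loading from the
#'   lower `member_qmax` quantile range of the loading distribution, so the
#'   planted hubs are unambiguously the top-loading genes of their module.
#' @param hub_loading Range (min, max) of planted-hub loadings, sitting
#'   above the member loading cap; with the default module size the hubs
#'   make up the top decile of realized loadings in a stress module.
#' @param hub_noise_factor Multiplier on `noise_sd` for planted hubs.
#'   Tightly regulated core genes track their regulon with less residual
#'   noise; this is what gives real hub genes their near-perfect module
#'   membership without implying enormous fold changes.
#' @param noise_sd Gene-level Gaussian noise sd on the latent scale.
#' @param activity_sd Per-sample biological noise sd on module activity
#'   (shared by a module's genes within a sample, i.e. coherent replicate
#'   variation); applied only where the module is active, so
#'   stress-specific modules stay silent under control.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param baseline_log_range Range of per-gene baseline natural-log means.
#' @param depth_range Range of per-library depth factors.
#' @param stress_modules Indices of the stress-specific modules.
#' @param stress_offset Condition offset of stress-module activity under
#'   salt: each stress gene is induced by `loading x stress_offset` on the
#'   latent scale in addition to its salt-time trend. This makes
#'   stress-responsive genes as variable overall as constitutive dynamic
#'   genes (they are silent in half the libraries) without altering their
#'   within-salt coherence.
#' @param n_hubs Planted hubs per stress module.
#' @param seed Mandatory integer seed; the generator is deterministic.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       n_modules = 6,
                       genes_per_module = 80,
                       conditions = c("control", "salt"),
                       time_h = c(0, 3, 6, 12, 24, 48),
                       replicates = 3,
                       loading_mean = 0.5,
                       loading_sd = 0.18,
                       neg_loading_prob = 0.2,
                       member_qmax = 0.85,
                       hub_loading = c(1.1, 1.3),
                       hub_noise_factor = 0.4,
                       noise_sd = 0.3,
                       activity_sd = 0.15,
                       dispersion = 0.05,
                       baseline_log_range = log(c(200, 2000)),
                       depth_range = c(0.7, 1.4),
                       stress_modules = c(5, 6),
                       stress_offset = 1.2,
                       n_hubs = 8,
                       seed = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$seed)) stop("sim_config: a seed is mandatory for reproducibility")
  if (cfg$n_modules * cfg$genes_per_module > cfg$n_genes)
    stop("sim_config: n_modules * genes_per_module exceeds n_genes")
  if (length(cfg$conditions) != 2L)
    stop("sim_config: exactly two conditions are supported")
  if (any(cfg$stress_modules > cfg$n_modules) || any(cfg$stress_modules < 1))
    stop("sim_config: stress_modules out of range")
  if (cfg$n_hubs > cfg$genes_per_module)
    stop("sim_config: n_hubs exceeds genes_per_module")
  if (cfg$noise_sd < 0) stop("sim_config: noise_sd must be non-negative")
  if (length(cfg$time_h) < 3L) stop("sim_config: need at least three time points")
  if (cfg$member_qmax <= 0 || cfg$member_qmax >= 1)
    stop("sim_config: member_qmax must lie in (0, 1)")
  if (cfg$hub_loading[1L] > cfg$hub_loading[2L] || cfg$hub_loading[1L] <= 0)
    stop("sim_config: hub_loading must be an increasing positive range")
  class(cfg) <- "sim_config"
  cfg
}

# Module activity profiles over the (condition, time) cells. Constitutive
# modules take the low-order orthogonal polynomial time trends, identical
# in both conditions; one extra constitutive module (beyond the available
# trends) becomes a pure condition-contrast module (down under control, up
# under salt, flat in time), orthogonal to every zero-mean trend. Stress
# modules are flat under control and share the highest-order trend under
# salt, separated from each other by condition offsets of alternating sign
# (salt-induced vs salt-repressed): they rewire into one coherent
# stress-state blob (so planted hubs saturate the same stress component)
# while their nearly uncorrelated global profiles keep them apart -- and
# orthogonal to the constitutive trends -- in the global clustering.
sim_module_activity <- function(cfg) {
  nt <- length(cfg$time_h)
  trends <- stats::contr.poly(nt)                # orthonormal, zero-mean
  trends <- trends * sqrt(nt - 1)                # unit sample variance
  n_stress <- length(cfg$stress_modules)
  constitutive <- setdiff(seq_len(cfg$n_modules), cfg$stress_modules)
  n_trend <- ncol(trends)
  n_shared <- n_trend - min(n_stress, 1L)
  if ((n_stress && n_trend < 1L) || length(constitutive) > n_shared + 1L)
    stop("too many modules for the number of time points")
  act <- array(0, dim = c(cfg$n_modules, 2L, nt),
               dimnames = list(NULL, cfg$conditions, paste0(cfg$time_h, "h")))
  for (i in seq_along(constitutive)) {
    if (i <= n_shared) {
      act[constitutive[i], 1L, ] <- trends[, i]
      act[constitutive[i], 2L, ] <- trends[, i]
    } else {
      act[constitutive[i], 1L, ] <- -1
      act[constitutive[i], 2L, ] <- 1
    }
  }
  for (j in seq_along(cfg$stress_modules)) {
    act[cfg$stress_modules[j], 1L, ] <- 0
    offset <- cfg$stress_offset * ceiling(j / 2) * (-1)^(j - 1)
    act[cfg$stress_modules[j], 2L, ] <- offset + trends[, n_trend]
  }
  act
}

#' Simulate a two-condition time-course RNA-seq experiment
#'
#' Draws negative-binomial counts whose latent (log) expression follows
#' planted module activity profiles: `latent = loading x activity + noise`,
#' `counts ~ NB(mean = exp(baseline + latent) x depth, dispersion)`.
#' Planted hubs in stress-specific modules carry the largest loadings, so
#' they emerge as the most connected genes of the stress-state network
#' while being absent from the normal-state network.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (genes x samples integer matrix), `sheet`
#'   (sample sheet data.frame), and `truth` (list: `genes` data.frame with
#'   gene_id/module/is_hub/loading, `activity` array, `latent` matrix).
#' @export
simulate_experiment <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  set.seed(cfg$seed)
  nt <- length(cfg$time_h)
  sheet <- expand.grid(replicate = seq_len(cfg$replicates),
                       time_h = cfg$time_h,
                       condition = cfg$conditions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet <- sheet[, c("condition", "time_h", "replicate")]
  tag <- ifelse(sheet$condition == cfg$conditions[1L], "ct", "ss")
  sheet$sample_id <- sprintf("%s_%dh_r%d", tag, sheet$time_h, sheet$replicate)
  sheet <- sheet[, c("sample_id", "condition", "time_h", "replicate")]
  n_samp <- nrow(sheet)

  n_mod_genes <- cfg$n_modules * cfg$genes_per_module
  gene_id <- sprintf("gene%04d", seq_len(cfg$n_genes))
  module <- c(rep(seq_len(cfg$n_modules), each = cfg$genes_per_module),
              rep(0L, cfg$n_genes - n_mod_genes))
  is_hub <- logical(cfg$n_genes)
  for (m in cfg$stress_modules) {
    first <- (m - 1L) * cfg$genes_per_module + 1L
    is_hub[first:(first + cfg$n_hubs - 1L)] <- TRUE
  }

  # gamma loading continuum; planted hubs occupy the top decile, ordinary
  # members the lower quantile range, via the inverse CDF
  shape <- (cfg$loading_mean / cfg$loading_sd)^2
  scale <- cfg$loading_sd^2 / cfg$loading_mean
  qload <- function(u) stats::qgamma(u, shape = shape, scale = scale)
  loading <- numeric(cfg$n_genes)
  members <- module > 0L & !is_hub
  loading[members] <- qload(stats::runif(sum(members), 0, cfg$member_qmax))
  loading[members] <- pmax(loading[members], 0.05)
  flip <- members & (stats::runif(cfg$n_genes) < cfg$neg_loading_prob)
  loading[flip] <- -loading[flip]
  loading[is_hub] <- stats::runif(sum(is_hub), cfg$hub_loading[1L],
                                  cfg$hub_loading[2L])

  act <- sim_module_activity(cfg)
  cond_idx <- match(sheet$condition, cfg$conditions)
  time_idx <- match(sheet$time_h, cfg$time_h)
  sample_activity <- matrix(0, nrow = cfg$n_modules, ncol = n_samp)
  for (s in seq_len(n_samp))
    sample_activity[, s] <- act[, cond_idx[s], time_idx[s]]
  # coherent biological replicate variation, only where a module is active
  active <- apply(act != 0, c(1L, 2L), any)      # module x condition
  active_sample <- active[, cond_idx, drop = FALSE]
  sample_activity <- sample_activity + active_sample *
    matrix(stats::rnorm(cfg$n_modules * n_samp, 0, cfg$activity_sd),
           nrow = cfg$n_modules)

  signal <- matrix(0, nrow = cfg$n_genes, ncol = n_samp)
  in_mod <- module > 0L
  signal[in_mod, ] <- loading[in_mod] * sample_activity[module[in_mod], , drop = FALSE]
  gene_noise_sd <- ifelse(is_hub, cfg$hub_noise_factor * cfg$noise_sd,
                          cfg$noise_sd)
  latent <- signal + matrix(stats::rnorm(cfg$n_genes * n_samp, 0, gene_noise_sd),
                            nrow = cfg$n_genes)
  dimnames(latent) <- list(gene_id, sheet$sample_id)

  baseline <- stats::runif(cfg$n_genes, cfg$baseline_log_range[1L],
                           cfg$baseline_log_range[2L])
  depth <- stats::runif(n_samp, cfg$depth_range[1L], cfg$depth_range[2L])
  mu <- exp(baseline + latent) * rep(depth, each = cfg$n_genes)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                   nrow = cfg$n_genes, dimnames = dimnames(latent))
  storage.mode(counts) <- "double"

  truth <- list(
    genes = data.frame(gene_id = gene_id,
                       module = ifelse(module > 0L, paste0("sim", module), "background"),
                       is_hub = is_hub, loading = loading,
                       stringsAsFactors = FALSE),
    activity = act,
    latent = latent
  )
  list(counts = counts, sheet = sheet, truth = truth, config = cfg)
}

#' Write a simulated experiment to disk in the pipeline's input formats
#'
#' Counts as TSV, sample sheet as CSV, ground truth as TSV and the
#' configuration as JSON.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             sheet = file.path(dir, "sample_sheet.csv"),
             truth = file.path(dir, "sim_truth.tsv"),
             config = file.path(dir, "sim_config.json"))
  write_matrix_tsv(sim$counts, paths[["counts"]])
  utils::write.csv(sim$sheet, paths[["sheet"]], row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth$genes, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Compare inferred modules and key genes against planted truth
#'
#' @param truth Truth list from [simulate_experiment()] (or its `genes`
#'   data.frame).
#' @param modules Named module-label vector ([cluster_modules()]); only
#'   genes present here enter the partition comparison.
#' @param keys Key-gene table ([identify_key_genes()]) or NULL.
#' @param include_background Keep genes whose true label is background in
#'   the partition comparison (their inferred "grey" then counts as
#'   agreement with a background cluster).
#' @return List: `ari` (adjusted Rand index between planted and inferred
#'   partitions), `hub_recall`, `hub_precision` (NA when no key genes), and
#'   counts `n_genes_compared`, `n_true_hubs`, `n_key_genes`.
#' @export
evaluate_recovery <- function(truth, modules, keys = NULL,
                              include_background = TRUE) {
  genes <- if (is.data.frame(truth)) truth else truth$genes
  common <- intersect(names(modules), genes$gene_id)
  true_lab <- genes$module[match(common, genes$gene_id)]
  inf_lab <- modules[common]
  if (!include_background) {
    keep <- true_lab != "background"
    true_lab <- true_lab[keep]
    inf_lab <- inf_lab[keep]
  }
  ari <- if (length(true_lab) >= 2L)
    mclust::adjustedRandIndex(true_lab, inf_lab) else NA_real_
  true_hubs <- genes$gene_id[genes$is_hub]
  key_ids <- if (is.null(keys)) character() else keys$gene_id
  tp <- length(intersect(key_ids, true_hubs))
  list(ari = ari,
       hub_recall = if (length(true_hubs)) tp / length(true_hubs) else NA_real_,
       hub_precision = if (length(key_ids)) tp / length(key_ids) else NA_real_,
       n_genes_compared = length(true_lab),
       n_true_hubs = length(true_hubs),
       n_key_genes = length(key_ids))
}
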