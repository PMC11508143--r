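#' Pipeline configuration
#'
#' Collects every tunable of the two-state co-expression workflow with the
#' study defaults: 95th-percentile variance filter, candidate soft powers
#' 1-20 at a scale-free fit cut of 0.9, minimum module size 35, edge weight
#' threshold 0.1 and a key-gene degree-change threshold of 80 percentage
#' points.
#'
#' @param counts_path TSV count matrix path.
#' @param sheet_path CSV sample sheet path.
#' @param out_dir Output directory for all artifacts.
#' @param gmt_path Optional GMT annotation file; enables per-module
#'   enrichment.
#' @param percentile Variance-filter percentile in `[0, 100)`.
#' @param powers Candidate soft-threshold powers.
#' @param r2_cut Scale-free fit index required of the chosen power.
#' @param power Fixed soft-threshold power. The default (NULL) selects the
#'   power from the scale-free fit of the global data; setting it pins the
#'   power instead, as practitioners do after inspecting the fit curve.
#'   The soft-threshold report is written either way.
#' @param min_module_size Smallest gene count kept as a module.
#' @param cut_height Absolute dendrogram cut height (NULL = use
#'   `cut_fraction`).
#' @param cut_fraction Cut height as a fraction of the maximum merge height.
#' @param edge_threshold Minimum TOM weight kept as a network edge.
#' @param key_threshold Degree-change percentage points a key gene must
#'   surpass.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the inputs are simulated).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path, sheet_path, out_dir,
                            gmt_path = NULL,
                            percentile = 95,
                            powers = 1:20,
                            r2_cut = 0.9,
                            power = NULL,
                            min_module_size = 35,
                            cut_height = NULL,
                            cut_fraction = 0.99,
                            edge_threshold = 0.1,
                            key_threshold = 80,
                            seed = 1) {
  cfg <- as.list(environment())
  if (cfg$percentile < 0 || cfg$percentile >= 100)
    stop("percentile must lie in [0, 100)")
  if (cfg$r2_cut <= 0 || cfg$r2_cut > 1) stop("r2_cut must lie in (0, 1]")
  if (cfg$edge_threshold <= 0 || cfg$edge_threshold > 1)
    stop("edge_threshold must lie in (0, 1]")
  if (cfg$key_threshold <= 0 || cfg$key_threshold > 100)
    stop("key_threshold must lie in (0, 100]")
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

# Correlation for a state network: genes constant within the state carry no
# co-expression information there and are dropped before correlating.
state_expression <- function(x, sheet, condition) {
  xs <- x[, sheet$sample_id[sheet$condition == condition], drop = FALSE]
  xs[row_variances(xs) > 0, , drop = FALSE]
}

#' Run the full two-state co-expression pipeline
#'
#' Reads counts and sample sheet, normalizes and filters, picks the soft
#' threshold on the global (all-sample) data, detects modules and
#' module-trait relationships, builds the global / normal-state /
#' stress-state networks with the same power, computes network statistics
#' and node centralities, derives the centrality-change table and key hub
#' genes, optionally runs per-module enrichment, and writes every artifact
#' plus a provenance manifest into `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results (filtered
#'   expression, soft-threshold report, modules, MTR table, networks,
#'   centrality tables, change table, key genes, manifest path).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(cfg$out_dir, name)
  written <- character()
  emit <- function(name, writer) {
    path <- outfile(name)
    writer(path)
    written <<- c(written, path)
    path
  }

  counts <- pipeline_stage("read_counts", read_counts(cfg$counts_path))
  sheet <- pipeline_stage("read_sample_sheet",
                          read_sample_sheet(cfg$sheet_path, counts = counts))
  conditions <- c("control", "salt")

  sf <- pipeline_stage("size_factors", estimate_size_factors(counts))
  emit("size_factors.tsv", function(p)
    utils::write.table(data.frame(sample_id = names(sf), size_factor = sf),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))
  x <- pipeline_stage("vst_transform", vst_transform(counts, sf))
  xf <- pipeline_stage("filter_by_variance",
                       filter_by_variance(x, cfg$percentile))
  emit("filtered_expression.tsv", function(p) write_matrix_tsv(xf, p))

  pick <- pipeline_stage("pick_soft_threshold",
                         pick_soft_threshold(xf, cfg$powers, cfg$r2_cut))
  emit("soft_threshold_report.tsv", function(p)
    utils::write.table(pick$report, p, sep = "\t", quote = FALSE, row.names = FALSE))
  beta <- if (is.null(cfg$power)) pick$power else cfg$power

  tom_global <- pipeline_stage("global_tom",
    tom_similarity(soft_adjacency(pearson_correlation(xf), beta)))
  modules <- pipeline_stage("cluster_modules",
    cluster_modules(tom_global, cfg$min_module_size, cfg$cut_height,
                    cfg$cut_fraction))
  emit("module_assignment.tsv", function(p)
    utils::write.table(data.frame(gene_id = names(modules), module = modules),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))

  me <- pipeline_stage("module_eigengenes", module_eigengenes(xf, modules))
  emit("module_eigengenes.tsv", function(p) write_matrix_tsv(me, p, "sample_id"))
  mtr <- pipeline_stage("module_trait_relationships",
    module_trait_relationships(me, trait_design(sheet)))
  emit("module_trait_relationships.tsv", function(p)
    utils::write.table(mtr, p, sep = "\t", quote = FALSE, row.names = FALSE))

  nets <- list()
  cents <- list()
  stats_rows <- list()
  state_tom <- list(global = tom_global)
  for (state in conditions) {
    xs <- pipeline_stage(paste0(state, "_expression"),
                         state_expression(xf, sheet, state))
    state_tom[[state]] <- pipeline_stage(paste0(state, "_tom"),
      tom_similarity(soft_adjacency(pearson_correlation(xs), beta)))
  }
  for (nm in names(state_tom)) {
    g <- pipeline_stage(paste0(nm, "_network"),
                        build_network(state_tom[[nm]], cfg$edge_threshold))
    nets[[nm]] <- g
    emit(paste0("edges_", nm, ".tsv"), function(p) write_edge_list(g, p))
    stats_rows[[nm]] <- cbind(network = nm, network_properties(g))
    ct <- node_centralities(g)
    cents[[nm]] <- ct
    emit(paste0("centrality_", nm, ".tsv"), function(p) {
      ct$module <- ifelse(ct$gene_id %in% names(modules),
                          modules[ct$gene_id], "grey")
      utils::write.table(ct[, c("gene_id", "module", "DG", "BW", "CN", "CC")],
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  emit("network_stats.tsv", function(p)
    utils::write.table(do.call(rbind, stats_rows), p, sep = "\t",
                       quote = FALSE, row.names = FALSE))

  changes <- pipeline_stage("centrality_change",
    centrality_change(normalize_centrality(cents$control),
                      normalize_centrality(cents$salt)))
  emit("centrality_change.tsv", function(p)
    utils::write.table(changes, p, sep = "\t", quote = FALSE, row.names = FALSE))
  keys <- pipeline_stage("identify_key_genes",
    identify_key_genes(changes, igraph::V(nets$global)$name, modules,
                       cfg$key_threshold))
  emit("key_genes.tsv", function(p)
    utils::write.table(keys, p, sep = "\t", quote = FALSE, row.names = FALSE))

  enrich <- NULL
  if (!is.null(cfg$gmt_path)) {
    ann <- pipeline_stage("read_gmt", read_gmt(cfg$gmt_path))
    universe <- intersect(rownames(xf), unique(unlist(ann$sets)))
    enrich <- pipeline_stage("enrichment", {
      per_mod <- lapply(setdiff(unique(modules), "grey"), function(m) {
        res <- hypergeom_enrich(names(modules)[modules == m], ann, universe)
        if (nrow(res)) cbind(module = m, res) else NULL
      })
      do.call(rbind, per_mod)
    })
    emit("enrichment.tsv", function(p)
      utils::write.table(enrich, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  cfg_path <- outfile("pipeline_config.json")
  cfg_json <- unclass(cfg)
  cfg_json$powers <- as.integer(cfg$powers)
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    chosen_power = beta,
    reached_r2_cut = pick$reached_cut,
    files = as.list(stats::setNames(unname(tools::md5sum(written)),
                                    basename(written)))
  )
  manifest_path <- outfile("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(size_factors = sf, expression = xf, soft_threshold = pick,
                 modules = modules, eigengenes = me, mtr = mtr,
                 networks = nets, centralities = cents,
                 network_stats = do.call(rbind, stats_rows),
                 changes = changes, key_genes = keys, enrichment = enrich,
                 manifest = manifest, manifest_path = manifest_path))
}
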