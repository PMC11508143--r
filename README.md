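# tscoex — two-state weighted gene co-expression network analysis

`tscoex` implements, as a tested R package plus a small analysis
workflow, the two-state weighted gene co-expression network (WGCNA)
pipeline used to find *stress-emergent hub genes* in time-series
RNA-seq: genes that are peripheral in the co-expression network built
from unstressed samples but become highly connected in the network built
from stressed samples. The motivating setting is a salt-tolerant rice
variety sampled at 0/3/6/12/24/48 h under control and saline soil with
three replicates (36 libraries); the package is generic over any
two-condition time-course count matrix. It is aimed at transcriptomics /
systems-biology analysts who want the whole chain — normalization to key
hub genes — scriptable, deterministic and unit-tested.

## The method

Starting from raw counts `k` (genes x samples) and a sample sheet:

1. **Normalize**: median-of-ratios size factors `s_j`; transform
   `x = log2(k/s + 1)`.
2. **Filter**: keep genes with per-gene variance at or above a percentile
   of the variance distribution (study setting: 95th; 38,993 genes ->
   1,950).
3. **Adjacency**: unsigned soft threshold `a_ij = |cor(x_i, x_j)|^beta`,
   with `beta` assessed by the scale-free topology fit (signed
   `R^2 = -sign(slope) * R^2` of the log-log connectivity regression;
   smallest power reaching 0.9).
4. **TOM**: topological overlap
   `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
   `l_ij = sum_u a_iu a_uj`; modules = average-linkage clusters of
   `1 - TOM` (static cut, minimum size 35, size-ranked color labels,
   "grey" = unassigned); module eigengenes and module-trait
   relationships (Pearson r with Student-t p, one indicator per
   condition x time group).
5. **Three networks** — global, normal-state, salt-state — built with the
   *same* power, thresholded at TOM >= 0.1; per network: node/edge
   counts, 2E/N, median degree, diameter of the largest component,
   average clustering, and per node the four centralities DG / BW / CN /
   CC (unweighted shortest paths, normalized per component).
6. **Key hub genes**: normalize each centrality by its within-network
   maximum (absent gene = 0); `delta% = (c_salt - c_normal) * 100`; a key
   gene is in the global network with `delta%(DG) > 80`, annotated with
   how many of the four measures pass.
7. **Enrichment**: hypergeometric over-representation of each module
   against user-supplied GMT terms, BH-adjusted.

A synthetic-data module (`sim_config()` / `simulate_experiment()`)
generates NB counts with planted modules, stress-specific rewiring and
planted hub genes, plus exported ground truth, so the entire pipeline is
testable offline; `evaluate_recovery()` scores module recovery (adjusted
Rand index) and hub precision/recall.

## Worked example

The `analysis/` scripts run the whole study on simulated data:

```sh
Rscript analysis/01_simulate_data.R     # inputs + truth -> results/sim_input/
Rscript analysis/02_run_pipeline.R      # all artifacts  -> results/pipeline/
Rscript analysis/03_evaluate_recovery.R # scores         -> results/recovery.tsv
```

Output of the run (seed 1):

```
simulated 1000 genes x 36 libraries (seed 1)
planted: 6 modules (2 stress-specific), 16 hub genes
filtered to 350 high-variance genes
scale-free pick: power 13 (cut reached: FALSE); networks built at power 10
modules: turquoise=65, blue=60, brown=59, yellow=56, green=55, red=43, grey=12
 network n_nodes n_edges average_degree median_degree diameter average_clustering
  global     125     811      12.976000             9        2          0.6803834
 control     145     279       3.848276             2        4          0.3052263
    salt     256    3094      24.171875            11        3          0.6566988
key hub genes (degree change > 80%): 23
module recovery ARI: 0.975 (over 350 filtered genes)
planted hub recall: 1.000, precision: 0.696 (23 key genes, 16 planted hubs)
```

Reading this: the six detected modules match the six planted ones almost
perfectly (ARI 0.975); the salt-state network is larger and denser than
the control network because the two stress-specific modules only wire up
under salt; all 16 planted hubs are recovered among the 23 genes whose
normalized degree rose by more than 80 percentage points from the normal
to the salt network. The per-module enrichment table flags each module's
own planted annotation term at adjusted p < 1e-50.

The equivalent single call from R:

```r
library(tscoex)
sim <- simulate_experiment(sim_config(seed = 1))
paths <- write_simulation(sim, "results/sim_input")
cfg <- pipeline_config(paths[["counts"]], paths[["sheet"]],
                       out_dir = "results/pipeline",
                       percentile = 65, power = 10, cut_fraction = 0.999)
res <- run_pipeline(cfg)
evaluate_recovery(sim$truth, res$modules, res$key_genes)
```

See `vignettes/two-state-coexpression.Rmd` for the model, every tunable
parameter, the generator's assumptions, and the reasoning behind the
synthetic-study settings (percentile 65, pinned power 10, cut fraction
0.999).

## Repository layout

```
R/                  package code (preprocess, WGCNA core, network stats,
                    two-state comparison, enrichment, simulator, pipeline)
tests/testthat/     unit, property and acceptance suites with brute-force
                    oracles (all-pairs BFS centralities, triple-loop TOM)
analysis/           numbered workflow scripts (simulate, run, evaluate)
scripts/            acceptance.R
vignettes/          methods vignette
```
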