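#!/usr/bin/env Rscript
# Score the pipeline's output against the planted ground truth: adjusted
# Rand index between planted and inferred module partitions, and
# precision/recall of the planted stress-emergent hubs among the key hub
# genes. Writes results/recovery.tsv.

suppressPackageStartupMessages(library(tscoex))

inp <- file.path("results", "sim_input")
pipe_dir <- file.path("results", "pipeline")

truth <- read.delim(file.path(inp, "sim_truth.tsv"), stringsAsFactors = FALSE)
mods_df <- read.delim(file.path(pipe_dir, "module_assignment.tsv"),
                      stringsAsFactors = FALSE)
modules <- setNames(mods_df$module, mods_df$gene_id)
keys <- read.delim(file.path(pipe_dir, "key_genes.tsv"),
                   stringsAsFactors = FALSE)

rec <- evaluate_recovery(truth, modules, keys)
out <- data.frame(metric = c("module_ari", "hub_recall", "hub_precision",
                             "n_genes_compared", "n_true_hubs", "n_key_genes"),
                  value = c(rec$ari, rec$hub_recall, rec$hub_precision,
                            rec$n_genes_compared, rec$n_true_hubs,
                            rec$n_key_genes))
write.table(out, file.path("results", "recovery.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("module recovery ARI: %.3f (over %d filtered genes)",
                rec$ari, rec$n_genes_compared))
message(sprintf("planted hub recall: %.3f, precision: %.3f (%d key genes, %d planted hubs)",
                rec$hub_recall, rec$hub_precision, rec$n_key_genes,
                rec$n_true_hubs))

key_mods <- table(keys$module)
message("key genes by module: ",
        paste(names(key_mods), key_mods, sep = "=", collapse = ", "))
message("measure combinations (1-4) among key genes: ",
        paste(names(table(keys$n_measures_passed)),
              table(keys$n_measures_passed), sep = "x", collapse = ", "))
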