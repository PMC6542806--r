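#!/usr/bin/env Rscript
# Step 3: positive Spearman co-occurrence network over the dominant set and
# ecological clusters (modules) by Louvain modularity; standardised cluster
# abundances per site.

suppressPackageStartupMessages(library(domitax))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

tab <- read_phylotype_table("results/data/table.tsv")
dres <- read_results_tsv("results/dominance.tsv")
dominant <- dres$phylotype_id[dres$is_global_dominant]

rel <- relative_abundance(tab)
sp <- spearman_all_pairs(rel[dominant, , drop = FALSE])
net <- build_network(sp$rho, sp$p)
net <- detect_modules(net, seed = seed)
write_results(net, "results/network.json", "json")

cat(sprintf("network: %d nodes, %d edges (rho > 0.40, p < 0.01, positive only)\n",
            length(net$nodes), nrow(net$edges)))
cat(sprintf("%d modules; the three largest group %.0f%% of dominant phylotypes\n",
            length(net$module_sizes),
            100 * sum(head(sort(net$module_sizes, decreasing = TRUE), 3)) /
              length(net$nodes)))

ca <- module_zscore_abundance(rel, net)
write_results(ca, "results/cluster_scores.tsv", "tsv")
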