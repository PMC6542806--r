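#!/usr/bin/env Rscript
# Step 2: classify globally dominant phylotypes (abundant + frequent + broad)
# and summarise the abundance-occupancy relationship.

suppressPackageStartupMessages(library(domitax))
tab <- read_phylotype_table("results/data/table.tsv")
meta <- read_metadata("results/data/metadata.csv",
                      c("aridity_index", "min_temperature", "max_temperature",
                        "precipitation_seasonality", "mdr", "uv", "ndvi",
                        "clay_silt", "ph", "total_c", "total_n", "total_p"))
al <- align_table_metadata(tab, meta, "strict")

res <- classify_dominant(al$table, al$meta)
write_results(res, "results/dominance.tsv", "tsv")

truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
det <- res$phylotype_id[res$is_global_dominant]
tp <- length(intersect(det, truth$dominant_ids))
cat(sprintf("%d of %d phylotypes globally dominant (%.2f%% of phylotypes, %.1f%% of reads)\n",
            length(det), nrow(res), 100 * length(det) / nrow(res),
            100 * sum(res$global_rel_abundance[res$is_global_dominant])))
cat(sprintf("against planted truth: precision %.3f, recall %.3f\n",
            tp / length(det), tp / length(truth$dominant_ids)))

ao <- abundance_occupancy(al$table, q = c(0.02, 0.5))
cat(sprintf("abundance-occupancy Pearson r = %.2f (p = %.2g, n = %d)\n",
            ao$pearson_r, ao$p_value, ao$n_used))
cat(sprintf("%.0f%% of phylotypes occur in <=2%% of samples; %.1f%% in >=50%%\n",
            100 * ao$occupancy_at_q[["occupancy_leq_0.02"]],
            100 * (1 - ao$occupancy_at_q[["occupancy_leq_0.5"]])))
write_results(ao$per_phylotype, "results/abundance_occupancy.tsv", "tsv")
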