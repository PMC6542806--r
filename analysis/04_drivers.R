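#!/usr/bin/env Rscript
# Step 4: environmental drivers of each ecological cluster: semi-partial
# Spearman correlations against 14 predictors (12 continuous + forest and
# grassland dummies), plus latitude/longitude-controlled partials.

suppressPackageStartupMessages(library(domitax))
meta <- read_metadata("results/data/metadata.csv",
                      c("aridity_index", "min_temperature", "max_temperature",
                        "precipitation_seasonality", "mdr", "uv", "ndvi",
                        "clay_silt", "ph", "total_c", "total_n", "total_p"))
scores_df <- read_results_tsv("results/cluster_scores.tsv")
scores <- as.matrix(scores_df[, -1, drop = FALSE])
rownames(scores) <- scores_df$sample_id
stopifnot(identical(rownames(scores), meta$sample_id))

eco <- encode_ecosystem(meta)
meta$forest <- eco[, "forest"]
meta$grassland <- eco[, "grassland"]
attr(meta, "ecosystem_flags") <- c("forest", "grassland")

ca <- structure(list(scores = scores), class = "cluster_abundance")
drv <- cluster_drivers(ca, meta)
write_results(drv, "results/drivers.tsv", "tsv")

big <- drv[!is.na(drv$rho) & abs(drv$rho) > 0.15 & drv$p < 0.01, ]
cat("strongest semi-partial associations (|rho| > 0.15, p < 0.01):\n")
for (i in seq_len(nrow(big))) {
  cat(sprintf("  %s ~ %-26s rho = %+.2f (spatially controlled: %+.2f)\n",
              big$module[i], big$predictor[i], big$rho[i], big$spatial_rho[i]))
}
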