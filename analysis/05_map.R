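#!/usr/bin/env Rscript
# Step 5: predict cluster abundance over a regular lat/lon grid (each cell
# carries the predictors of its nearest surveyed site, emulating raster
# extraction) and evaluate predicted vs observed scores by 10-fold CV and
# by resubstitution.

suppressPackageStartupMessages(library(domitax))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

meta <- read_metadata("results/data/metadata.csv",
                      c("aridity_index", "min_temperature", "max_temperature",
                        "precipitation_seasonality", "mdr", "uv", "ndvi",
                        "clay_silt", "ph", "total_c", "total_n", "total_p"))
eco <- encode_ecosystem(meta)
meta$forest <- eco[, "forest"]
meta$grassland <- eco[, "grassland"]
predictors <- c(attr(meta, "predictors"), "forest", "grassland")

scores_df <- read_results_tsv("results/cluster_scores.tsv")
scores <- as.matrix(scores_df[, -1, drop = FALSE])
rownames(scores) <- scores_df$sample_id

fit <- fit_distribution_model(scores, as.data.frame(meta)[, predictors],
                              seed = seed)

# regular 4-degree grid over the surveyed extent; nearest-site predictors
grid_pts <- expand.grid(latitude = seq(-80, 64, by = 4),
                        longitude = seq(-170, 170, by = 4))
nearest <- apply(grid_pts, 1, function(g) {
  which.min((meta$latitude - g[1])^2 + (meta$longitude - g[2])^2)
})
grid <- cbind(cell_id = seq_len(nrow(grid_pts)), grid_pts,
              as.data.frame(meta)[nearest, predictors])

pe_cv <- predict_and_evaluate(fit, grid = grid, scheme = "kfold", seed = seed)
pe_rs <- predict_and_evaluate(fit, scheme = "resubstitution")
eval_tab <- rbind(pe_cv$evaluation, pe_rs$evaluation)
write_results(eval_tab, "results/map_evaluation.tsv", "tsv")
write.csv(pe_cv$grid_predictions, "results/map_predictions.csv", row.names = FALSE)

cat("predicted vs observed cluster abundance (Spearman):\n")
for (i in seq_len(nrow(eval_tab))) {
  cat(sprintf("  %s  rho = %.2f (p = %.2g, %s)\n", eval_tab$module[i],
              eval_tab$rho[i], eval_tab$p[i], eval_tab$scheme[i]))
}
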