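#!/usr/bin/env Rscript
# Step 1: simulate the survey. Generates the default 235-site, nine-biome
# design with 2,000 phylotypes (30 planted dominant generalists split over
# mesic/forest/dry niche groups) plus a genome trait table with three
# planted enriched gene classes, and writes everything under results/data/.

suppressPackageStartupMessages(library(domitax))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

design <- simulation_design(rng_seed = seed)
meta <- generate_sites(design)
com <- generate_community(design, meta)

write.table(data.frame(phylotype_id = rownames(com$table),
                       as.data.frame(unclass(com$table)), check.names = FALSE),
            "results/data/table.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.csv(as.data.frame(meta), "results/data/metadata.csv", row.names = FALSE)

truth <- com$truth
truth$expected_props <- NULL  # large; regenerate from the design when needed
jsonlite::write_json(truth, "results/data/truth.json", auto_unbox = TRUE, digits = NA)

classes <- c(paste0("caz_", 1:6), paste0("pep_", 1:4), paste0("stress_", 1:5),
             paste0("nutrient_", 1:5))
gt <- generate_trait_table(n_per_group = 11, classes = classes,
                           enriched = c("stress_1", "stress_2", "nutrient_1"),
                           fold_change = 2, seed = seed)
write.table(as.data.frame(gt$traits), "results/data/traits.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(gt$truth, "results/data/traits_truth.json", auto_unbox = TRUE)

cat(sprintf("simulated %d phylotypes x %d sites over %d biomes (seed %d)\n",
            nrow(com$table), ncol(com$table), length(design$biome_names), seed))
cat(sprintf("planted %d dominant generalists; mean depth %.0f reads/site\n",
            design$n_dominant, mean(colSums(com$table))))
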