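# domitax

Tools for identifying **globally dominant soil fungal phylotypes** in a
multi-biome amplicon survey and characterising their ecology: which taxa are
dominant, how they cluster by co-occurrence, what environmental variables
drive each cluster, where each cluster is expected to occur, and whether
dominant genomes carry distinctive functional gene repertoires.

The package is aimed at microbial ecologists working with phylotype-by-sample
count tables (ITS/16S OTU or ASV tables) plus per-sample environmental
metadata, and at methodologists who want a fully testable reference
implementation: a built-in Dirichlet-multinomial community simulator plants
known dominant generalists, niche-structured specialists and trait-enriched
genome groups, so every stage of the pipeline is validated against ground
truth.

## The statistics at the core

**Dominance.** A phylotype is globally dominant when it is (i) *abundant* —
in the top 10% of phylotypes by share of total reads; (ii) *frequent* —
present in ≥ 1/3 of the samples of a biome; and (iii) *broad* — abundant and
frequent in ≥ ⌈B/2⌉ of the B surveyed biomes. All three thresholds are
configurable (`run_config()`), with `ceiling()` used so "at least one third"
and "at least half" hold exactly.

**Ecological clusters.** Over the dominant set, all pairwise Spearman rank
correlations are computed across samples; edges require ρ > 0.40 and
p < 0.01 (positive correlations only), and modules come from Louvain
modularity optimisation on the ρ-weighted graph. Cluster abundance per
sample is the mean z-score of member taxa (each taxon standardised to
mean 0, SD 1 across samples).

**Drivers.** For each cluster and each of 14 environmental predictors, the
semi-partial Spearman correlation r_y(x·Z) is reported — ranks first, the
other 13 predictors residualised out of the target predictor — plus a full
partial Spearman correlation controlling latitude and longitude, to separate
environmental signal from spatial autocorrelation.

**Mapping.** A linear model on standardised predictors predicts cluster
abundance over an environmental grid, with predictions clamped to the
training range and predicted-vs-observed Spearman ρ reported under 10-fold
cross-validation and resubstitution.

**Genome traits.** Gene-class counts standardised to genome size are
compared between dominant and non-dominant genome groups with a label
permutation test (difference in means, two-sided,
p = (1 + #{|perm| ≥ |obs|})/(1 + B), BH-corrected across classes) and ranked
by Cohen's d.

## Worked example

The `analysis/` directory is a numbered workflow over the package functions;
each step reads its predecessors' outputs from `results/` and states what it
found:

```sh
Rscript analysis/01_simulate.R --seed 1   # survey: table, metadata, truth, traits
Rscript analysis/02_dominance.R           # dominance classification
Rscript analysis/03_network.R --seed 1    # co-occurrence network and modules
Rscript analysis/04_drivers.R             # semi-partial driver correlations
Rscript analysis/05_map.R --seed 1        # grid prediction and evaluation
Rscript analysis/06_traits.R --seed 1     # genome trait comparison
```

With seed 1 this prints, among other things:

```
30 of 2000 phylotypes globally dominant (1.50% of phylotypes, 18.7% of reads)
against planted truth: precision 1.000, recall 1.000
abundance-occupancy Pearson r = 0.72 (p = 9.7e-188, n = 1192)
66% of phylotypes occur in <=2% of samples; 1.5% in >=50%
network: 30 nodes, 201 edges (rho > 0.40, p < 0.01, positive only)
3 modules; the three largest group 100% of dominant phylotypes
  M1 ~ aridity_index              rho = -0.33 (spatially controlled: -0.54)
  M2 ~ forest                     rho = +0.22 (spatially controlled: +0.25)
  M1  rho = 0.90 (p = 8.6e-87, kfold)
3 of 20 gene classes differ at q < 0.05: stress_1, stress_2, nutrient_1
```

Reading: the 30 planted dominant generalists are exactly the 30 detected
(1.5% of the phylotype pool holding ~19% of all reads, against a backdrop
where two thirds of taxa occur in under 2% of sites); they resolve into
three co-occurrence modules matching the planted mesic/forest/dry niche
groups; the mesic module (M1) tracks the aridity index negatively and the
forest module responds to the forest flag; cross-validated maps reproduce
observed cluster abundance at ρ ≈ 0.7–0.9; and the trait test flags exactly
the three gene classes planted at 2× enrichment.

Equivalent programmatic use:

```r
library(domitax)
design <- simulation_design(rng_seed = 1)
meta   <- generate_sites(design)
com    <- generate_community(design, meta)
dres   <- classify_dominant(com$table, meta, run_config())
subset(dres, is_global_dominant)[, c("phylotype_id", "abundance_rank",
                                     "occupancy", "breadth")]
```

Real data enter through `read_phylotype_table()` (TSV, either orientation),
`read_metadata()` (CSV/TSV with coordinates, biome and named predictors) and
`read_trait_table()`, followed by `align_table_metadata()`.

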