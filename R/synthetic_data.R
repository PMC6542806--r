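#' Simulation design for a survey-style fungal community dataset
#'
#' Describes a multi-biome soil survey: sites per biome, taxon pool, planted
#' dominant generalists, niche-structured specialists on an aridity-like
#' gradient, sequencing depth and count overdispersion. Defaults emulate a
#' 235-site, nine-biome global survey with the biome sample sizes of such a
#' campaign (boreal 3, cold forest 18, cold grassland 22, dry grassland 42,
#' dry forest 60, grassland 41, shrubland 15, temperate forest 27, tropical
#' forest 7).
#'
#' @param n_sites total number of sites.
#' @param biome_names names of the biomes surveyed.
#' @param sites_per_biome integer vector (same order as `biome_names`)
#'   summing to `n_sites`.
#' @param n_taxa total phylotype pool size.
#' @param n_dominant number of planted dominant generalists.
#' @param dominant_biome_breadth minimum number of biomes a planted dominant
#'   is built to span; must be at least half the biomes (rounded up).
#' @param depth_lognormal_params c(mu, sigma) of the per-sample read depth
#'   lognormal.
#' @param niche_width Gaussian niche width of specialist taxa on the [0, 1]
#'   aridity axis.
#' @param dominant_niche_width (much wider) niche width of planted dominants.
#' @param dispersion Dirichlet concentration: per-sample taxon proportions
#'   are drawn Dirichlet(dispersion x expected proportions); smaller values
#'   give stronger overdispersion.
#' @param base_sdlog sdlog of the lognormal base-abundance (rank-abundance)
#'   curve for specialist taxa.
#' @param forest_boost multiplier strength of the forest-flag interaction for
#'   the forest-preferring dominant group.
#' @param predictor_noise_sd site-level Gaussian noise SD on the aridity
#'   scale (other predictors are scaled proportionally).
#' @param rng_seed integer seed; sites use it directly, the community draw
#'   uses `rng_seed + 1`.
#' @return a validated list of class `simulation_design`.
#' @export
simulation_design <- function(n_sites = 235L,
                              biome_names = c("boreal", "cold forest",
                                              "cold grassland", "dry grassland",
                                              "dry forest", "grassland",
                                              "shrubland", "temperate forest",
                                              "tropical forest"),
                              sites_per_biome = c(3L, 18L, 22L, 42L, 60L,
                                                  41L, 15L, 27L, 7L),
                              n_taxa = 2000L,
                              n_dominant = 30L,
                              dominant_biome_breadth = NULL,
                              depth_lognormal_params = c(mu = log(20000), sigma = 0.5),
                              niche_width = 0.05,
                              dominant_niche_width = 0.27,
                              dispersion = 300,
                              base_sdlog = 3.0,
                              forest_boost = 2.0,
                              predictor_noise_sd = 0.04,
                              rng_seed = 1L) {
  n_biomes <- length(biome_names)
  dominant_biome_breadth <- dominant_biome_breadth %||% ceiling(n_biomes / 2)
  if (length(sites_per_biome) != n_biomes) {
    stop2("sites_per_biome must match biome_names (%d biomes)", n_biomes)
  }
  if (sum(sites_per_biome) != n_sites) {
    stop2("sites_per_biome sums to %d, not n_sites = %d",
          sum(sites_per_biome), n_sites)
  }
  if (n_dominant >= n_taxa) stop2("n_dominant must be < n_taxa")
  if (dominant_biome_breadth < ceiling(n_biomes / 2)) {
    stop2("dominant_biome_breadth must be at least ceil(n_biomes / 2) = %d",
          ceiling(n_biomes / 2))
  }
  if (niche_width <= 0 || dominant_niche_width <= 0 || dispersion <= 0) {
    stop2("niche widths and dispersion must be positive")
  }
  structure(list(
    n_sites = as.integer(n_sites), biome_names = biome_names,
    sites_per_biome = as.integer(sites_per_biome),
    n_taxa = as.integer(n_taxa), n_dominant = as.integer(n_dominant),
    dominant_biome_breadth = as.integer(dominant_biome_breadth),
    depth_lognormal_params = depth_lognormal_params,
    niche_width = niche_width, dominant_niche_width = dominant_niche_width,
    dispersion = dispersion, base_sdlog = base_sdlog,
    forest_boost = forest_boost, predictor_noise_sd = predictor_noise_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_design")
}

# characteristic positions of each default biome on two latent climate axes
# in [0, 1]: aridity (higher = drier) and thermal (higher = warmer); unknown
# biomes are spread evenly along both as a fallback
biome_climate_positions <- function(biomes) {
  aridity <- c("tropical forest" = 0.05, "boreal" = 0.15, "cold forest" = 0.25,
               "temperate forest" = 0.35, "cold grassland" = 0.45,
               "grassland" = 0.55, "dry forest" = 0.70, "shrubland" = 0.85,
               "dry grassland" = 0.95)
  thermal <- c("tropical forest" = 0.90, "boreal" = 0.05, "cold forest" = 0.15,
               "temperate forest" = 0.50, "cold grassland" = 0.20,
               "grassland" = 0.60, "dry forest" = 0.75, "shrubland" = 0.55,
               "dry grassland" = 0.80)
  a <- aridity[biomes]
  t <- thermal[biomes]
  if (anyNA(a)) a[is.na(a)] <- seq(0.1, 0.9, length.out = sum(is.na(a)))
  if (anyNA(t)) t[is.na(t)] <- seq(0.9, 0.1, length.out = sum(is.na(t)))
  list(aridity = setNames(as.numeric(a), biomes),
       thermal = setNames(as.numeric(t), biomes))
}

# continuous predictors as linear responses to the two climate axes; dry
# sites: more seasonal, higher UV/pH, less green; warm sites: hotter; mesic
# soils C/N-richer. Two axes keep the predictor set from collapsing onto a
# single gradient, as in real multi-biome surveys.
predictor_specs <- function() {
  data.frame(
    name = c("aridity_index", "min_temperature", "max_temperature",
             "precipitation_seasonality", "mdr", "uv", "ndvi", "clay_silt",
             "ph", "total_c", "total_n", "total_p"),
    intercept = c(0, -10, 8, 20, 8, 120, 0.80, 55, 5.5, 3.2, 0.28, 0.60),
    slope_a = c(1, 0, 8, 40, 8, 40, -0.55, -25, 2.5, -2.6, -0.20, -0.10),
    slope_t = c(0, 25, 20, 0, -2, 80, 0, 0, 0, 0.6, 0.05, -0.15),
    stringsAsFactors = FALSE
  )
}

#' Generate survey site metadata
#'
#' Each biome gets a characteristic mean for every predictor (a linear
#' response to its aridity position plus a biome-specific offset) and sites
#' scatter around those means with Gaussian noise. `aridity_index` follows a
#' clean monotone gradient from mesic- to dryland-type biomes (no biome
#' offsets). Latitude/longitude are drawn from disjoint per-biome boxes
#' ordered along the gradient, so space and environment are autocorrelated as
#' in a real survey. Forest/grassland flags derive from the biome.
#'
#' @param design a [simulation_design].
#' @return a [sample_metadata] data.frame with attribute `"biome_means"`.
#' @export
generate_sites <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  specs <- predictor_specs()
  biomes <- design$biome_names
  pos <- biome_climate_positions(biomes)
  a <- pos$aridity
  th <- pos$thermal
  with_rng_seed(design$rng_seed, {
    scale_k <- pmax(abs(specs$slope_a), abs(specs$slope_t))
    # biome-level offsets (part of the biome mean, not site noise)
    offsets <- vapply(seq_len(nrow(specs)), function(k) {
      if (specs$name[k] == "aridity_index") rep(0, length(biomes))
      else rnorm(length(biomes), 0, 0.08 * scale_k[k])
    }, numeric(length(biomes)))
    biome_means <- vapply(seq_len(nrow(specs)), function(k) {
      specs$intercept[k] + specs$slope_a[k] * a + specs$slope_t[k] * th +
        offsets[, k]
    }, numeric(length(biomes)))
    dimnames(biome_means) <- list(biomes, specs$name)

    biome_of_site <- rep(biomes, design$sites_per_biome)
    n <- design$n_sites
    pred <- vapply(seq_len(nrow(specs)), function(k) {
      # aridity stays a tight gradient (the community responds to it);
      # the other predictors carry broader site-level variation of their own
      mult <- if (specs$name[k] == "aridity_index") 1 else 3
      noise_sd <- mult * design$predictor_noise_sd * scale_k[k]
      biome_means[biome_of_site, k] + rnorm(n, 0, noise_sd)
    }, numeric(n))
    colnames(pred) <- specs$name

    # disjoint spatial boxes, ordered along the aridity gradient
    rank_a <- rank(a, ties.method = "first")
    lat0 <- -80 + 17 * (rank_a - 1)
    lon0 <- -170 + 36 * ((rank_a - 1) %% 9)
    lat <- lat0[biome_of_site] + runif(n, 0, 8)
    lon <- lon0[biome_of_site] + runif(n, 0, 24)

    df <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      biome = biome_of_site,
      latitude = lat, longitude = lon,
      pred,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    eco <- encode_ecosystem(df, types = c("forest", "grassland"))
    df$forest <- eco[, "forest"]
    df$grassland <- eco[, "grassland"]
    meta <- sample_metadata(df, specs$name)
    attr(meta, "biome_means") <- biome_means
    meta
  })
}

#' Generate a phylotype count table with planted ground truth
#'
#' Expected relative abundance of taxon i in site j is proportional to
#' `base_i * exp(-(aridity_j - optimum_i)^2 / (2 * width_i^2))`. Specialist
#' taxa get lognormal base abundances, uniform niche optima and narrow
#' widths; planted dominants get top-decile bases and a wide, near-flat
#' niche, and are split into three groups (mesic / forest / dry optima; the
#' forest group additionally responds to the forest flag), recorded as
#' `module_membership`. Counts are Dirichlet-multinomial per site with
#' lognormal depths (zero depths redrawn).
#'
#' @param design a [simulation_design].
#' @param meta site metadata from [generate_sites] under the same design.
#' @return list with `table` (a [phylotype_table]) and `truth` (list:
#'   `dominant_ids`, `taxon_niche_optima`, `module_membership`,
#'   `expected_props` matrix, `base_abundance`).
#' @export
generate_community <- function(design, meta) {
  stopifnot(inherits(design, "simulation_design"))
  n_taxa <- design$n_taxa
  n_dom <- design$n_dominant
  n_sites <- nrow(meta)
  aridity <- meta$aridity_index
  forest_flag <- meta$forest
  with_rng_seed(design$rng_seed + 1L, {
    ids <- sprintf("PT%05d", seq_len(n_taxa))
    dom_idx <- sort(sample.int(n_taxa, n_dom))
    dominant_ids <- ids[dom_idx]

    base <- rlnorm(n_taxa, 0, design$base_sdlog)
    # planted dominants: top-decile base abundance
    base[dom_idx] <- stats::qlnorm(runif(n_dom, 0.90, 0.98), 0, design$base_sdlog)

    optima <- runif(n_taxa, -0.05, 1.05)
    widths <- rep(design$niche_width, n_taxa)
    groups <- rep(c("mesic", "forest", "dry"), length.out = n_dom)
    group_opt <- c(mesic = 0.12, forest = 0.50, dry = 0.88)
    optima[dom_idx] <- group_opt[groups]
    widths[dom_idx] <- design$dominant_niche_width

    niche <- exp(-outer(optima, aridity, "-")^2 / (2 * widths^2))
    # forest-group dominants co-respond to the forest flag
    f_rows <- dom_idx[groups == "forest"]
    niche[f_rows, ] <- niche[f_rows, , drop = FALSE] *
      rep(1 + design$forest_boost * forest_flag, each = length(f_rows))

    expected <- base * niche
    expected <- sweep(expected, 2, colSums(expected), "/")

    mu <- design$depth_lognormal_params[[1]]
    sigma <- design$depth_lognormal_params[[2]]
    depth <- round(rlnorm(n_sites, mu, sigma))
    while (any(depth == 0)) {
      depth[depth == 0] <- round(rlnorm(sum(depth == 0), mu, sigma))
    }

    counts <- matrix(0L, n_taxa, n_sites, dimnames = list(ids, meta$sample_id))
    finite_disp <- is.finite(design$dispersion)
    if (finite_disp) {
      alpha <- design$dispersion * expected
      gdraw <- matrix(rgamma(length(alpha), shape = alpha), n_taxa, n_sites)
    }
    for (j in seq_len(n_sites)) {
      pj <- if (finite_disp && sum(gdraw[, j]) > 0) {
        gdraw[, j] / sum(gdraw[, j])
      } else {
        expected[, j]
      }
      counts[, j] <- rmultinom(1, size = depth[j], prob = pj)
    }

    truth <- list(
      dominant_ids = dominant_ids,
      taxon_niche_optima = setNames(optima, ids),
      module_membership = setNames(groups, dominant_ids),
      expected_props = expected,
      base_abundance = setNames(base, ids)
    )
    list(table = phylotype_table(counts), truth = truth)
  })
}

#' Generate a synthetic genome trait table
#'
#' Poisson gene-class counts per genome; the first (dominant) group's mean is
#' multiplied by `fold_change` for the enriched classes. Genome sizes are
#' lognormal and total gene counts scale with size. With the default equal
#' `size_meanlog` and `fold_change = 1` the two groups are exchangeable, so
#' permutation p-values are uniform; set a larger second value to emulate the
#' bigger genomes of saprotrophic basidiomycetes.
#'
#' @param n_per_group genomes per group.
#' @param classes character vector of gene-class names.
#' @param enriched subset of `classes` enriched in the dominant group.
#' @param fold_change enrichment factor (> 0; 1 = no enrichment).
#' @param base_class_mean Poisson mean of a class count in the baseline group.
#' @param base_genome_genes mean total gene count of a 35 Mb genome.
#' @param group_labels length-2 labels, dominant group first.
#' @param size_meanlog length-2 meanlog of the genome-size lognormal per
#'   group (default both log(35) Mb).
#' @param seed integer seed.
#' @return list with `traits` (a `trait_table`) and `truth`
#'   (`trait_enriched_classes`).
#' @export
generate_trait_table <- function(n_per_group = 10L, classes,
                                 enriched = character(0), fold_change = 2,
                                 base_class_mean = 50,
                                 base_genome_genes = 10000L,
                                 group_labels = c("dominant_asco",
                                                  "nondominant_basidio"),
                                 size_meanlog = c(log(35), log(35)),
                                 seed = 1L) {
  if (!all(enriched %in% classes)) stop2("enriched classes must be a subset of classes")
  if (fold_change <= 0) stop2("fold_change must be > 0")
  n <- 2L * as.integer(n_per_group)
  with_rng_seed(seed, {
    group <- rep(group_labels, each = n_per_group)
    size_meanlog <- ifelse(group == group_labels[1], size_meanlog[1],
                           size_meanlog[2])
    genome_size <- rlnorm(n, size_meanlog, 0.2)
    total_genes <- round(base_genome_genes * genome_size / 35 *
                           exp(rnorm(n, 0, 0.05)))
    means <- matrix(base_class_mean, n, length(classes),
                    dimnames = list(NULL, classes))
    means[group == group_labels[1], classes %in% enriched] <-
      base_class_mean * fold_change
    counts <- matrix(rpois(length(means), means), n, length(classes),
                     dimnames = list(NULL, classes))
    df <- data.frame(
      genome_id = sprintf("G%03d", seq_len(n)),
      group = group,
      genome_size_mb = genome_size,
      total_genes = pmax(total_genes, apply(counts, 1, max) + 1L),
      counts,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    list(traits = trait_table(df), truth = list(trait_enriched_classes = enriched))
  })
}
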