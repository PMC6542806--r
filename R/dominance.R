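#' Per-sample relative abundances
#'
#' @param table a [phylotype_table].
#' @return numeric matrix, phylotypes x samples, each column summing to 1.
#' @export
relative_abundance <- function(table) {
  sweep(unclass(table), 2, colSums(table), "/")
}

#' Classify globally dominant phylotypes
#'
#' Applies the three dominance criteria: a phylotype is *abundant* if it falls
#' in the top `top_abundance_fraction` of phylotypes ranked by total reads
#' (pooled over all samples by default); *dominant in a biome* if it is
#' abundant and occurs in at least `min_biome_frequency` of that biome's
#' samples; and *globally dominant* if it is dominant in at least
#' `ceil(min_breadth_fraction * n_biomes)` biomes. Fractional thresholds are
#' honoured with `ceiling()` so "at least one third" and "at least half" hold
#' exactly; phylotypes tied with the boundary total are all included.
#'
#' @param table a [phylotype_table], aligned with `meta`.
#' @param meta a [sample_metadata] data.frame, samples in table column order.
#' @param cfg a [run_config].
#' @return a data.frame of class `dominance_result`, one row per phylotype,
#'   with total reads, global relative abundance, abundance rank (min-tie),
#'   abundance/occupancy flags, per-biome frequency (`freq_<biome>`) and
#'   dominance (`dom_<biome>`) columns, habitat breadth and the global flag.
#' @export
classify_dominant <- function(table, meta, cfg = run_config()) {
  if (!identical(colnames(table), meta$sample_id)) {
    stop2("table and metadata are not aligned; run align_table_metadata() first")
  }
  counts <- unclass(table)
  if (!is.null(cfg$rarefy_to)) {
    if (!requireNamespace("vegan", quietly = TRUE)) {
      stop2("rarefy_to requires the vegan package")
    }
    keep <- colSums(counts) >= cfg$rarefy_to
    if (!all(keep)) {
      dtx_log("rarefaction dropped %d of %d samples below depth %d",
              sum(!keep), ncol(counts), cfg$rarefy_to)
      counts <- counts[, keep, drop = FALSE]
      meta <- meta[keep, , drop = FALSE]
    }
    counts <- t(with_rng_seed(cfg$rng_seed,
                              vegan::rrarefy(t(counts), cfg$rarefy_to)))
  }
  biomes <- sort(unique(meta$biome))
  n_per_biome <- table(factor(meta$biome, levels = biomes))
  if (any(n_per_biome == 0)) {
    stop2("biome(s) with zero samples after alignment: %s",
          paste(biomes[n_per_biome == 0], collapse = ", "))
  }
  n_phy <- nrow(counts)
  totals <- rowSums(counts)
  rel_global <- totals / sum(totals)
  abundance_rank <- rank(-totals, ties.method = "min")
  cutoff <- ceiling(cfg$top_abundance_fraction * n_phy)
  boundary <- sort(totals, decreasing = TRUE)[cutoff]
  is_abundant <- totals >= boundary
  n_tied_extra <- sum(is_abundant) - cutoff
  if (n_tied_extra > 0) {
    dtx_log("abundance cutoff rank %d: %d extra phylotype(s) tied at the boundary",
            cutoff, n_tied_extra)
  }

  presence <- counts > 0
  freq <- vapply(biomes, function(b) {
    rowMeans(presence[, meta$biome == b, drop = FALSE])
  }, numeric(n_phy))
  colnames(freq) <- biomes

  if (cfg$abundance_scope == "biome") {
    abundant_mat <- vapply(biomes, function(b) {
      tb <- rowSums(counts[, meta$biome == b, drop = FALSE])
      co <- sort(tb, decreasing = TRUE)[cutoff]
      tb >= co
    }, logical(n_phy))
  } else {
    abundant_mat <- matrix(is_abundant, n_phy, length(biomes))
  }
  dom <- abundant_mat & (freq >= cfg$min_biome_frequency)
  colnames(dom) <- biomes
  breadth <- rowSums(dom)
  min_breadth <- ceiling(cfg$min_breadth_fraction * length(biomes))
  is_global <- breadth >= min_breadth

  res <- data.frame(
    phylotype_id = rownames(counts),
    total_reads = unname(totals),
    global_rel_abundance = unname(rel_global),
    abundance_rank = unname(abundance_rank),
    is_abundant = unname(is_abundant),
    occupancy = unname(rowMeans(presence)),
    stringsAsFactors = FALSE
  )
  for (b in biomes) res[[paste0("freq_", b)]] <- unname(freq[, b])
  for (b in biomes) res[[paste0("dom_", b)]] <- unname(dom[, b])
  res$breadth <- unname(breadth)
  res$is_global_dominant <- unname(is_global)
  attr(res, "biomes") <- biomes
  attr(res, "min_breadth") <- min_breadth
  attr(res, "abundance_cutoff_rank") <- cutoff
  class(res) <- c("dominance_result", "data.frame")
  dtx_log("%d of %d phylotypes globally dominant (breadth >= %d of %d biomes)",
          sum(is_global), n_phy, min_breadth, length(biomes))
  res
}

#' Abundance-occupancy relationship
#'
#' Computes, per phylotype, the mean relative abundance across samples and
#' the occupancy (fraction of samples with nonzero counts), the Pearson
#' correlation between log mean abundance and occupancy, and the fraction of
#' phylotypes found in at most a given fraction of samples.
#'
#' @param table a [phylotype_table].
#' @param q numeric vector of occupancy fractions to summarise (defaults:
#'   2% and 50% of samples).
#' @return list with `per_phylotype` (data.frame), `pearson_r`, `p_value`,
#'   `n_used` (phylotypes with nonzero total), `occupancy_at_q` (named
#'   fractions) and `degenerate` (TRUE when a correlation was undefined).
#' @export
abundance_occupancy <- function(table, q = c(0.02, 0.5)) {
  if (nrow(table) < 3) stop2("need at least 3 phylotypes")
  rel <- relative_abundance(table)
  mean_rel <- rowMeans(rel)
  occ <- rowMeans(unclass(table) > 0)
  per <- data.frame(phylotype_id = rownames(table),
                    mean_rel_abundance = unname(mean_rel),
                    occupancy = unname(occ),
                    stringsAsFactors = FALSE)
  keep <- mean_rel > 0
  x <- log(mean_rel[keep])
  y <- occ[keep]
  degenerate <- (sd(x) == 0 || sd(y) == 0 || sum(keep) < 3)
  if (degenerate) {
    r <- NA_real_
    p <- NA_real_
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  frac_leq <- vapply(q, function(qi) mean(occ <= qi), numeric(1))
  names(frac_leq) <- paste0("occupancy_leq_", q)
  list(per_phylotype = per, pearson_r = r, p_value = p, n_used = sum(keep),
       occupancy_at_q = frac_leq, degenerate = degenerate)
}
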