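options(domitax.verbose = FALSE)

# small random count table with a named biome assignment
make_toy_table <- function(n_phy = 20, n_samp = 10, seed = 1, lambda = 5) {
  set.seed(seed)
  counts <- matrix(rpois(n_phy * n_samp, lambda), n_phy, n_samp,
                   dimnames = list(sprintf("P%02d", seq_len(n_phy)),
                                   sprintf("S%02d", seq_len(n_samp))))
  # guarantee nonzero column sums
  counts[1, colSums(counts) == 0] <- 1
  counts
}

toy_meta <- function(sample_ids, biomes) {
  sample_metadata(data.frame(
    sample_id = sample_ids,
    biome = biomes,
    latitude = seq(-40, 40, length.out = length(sample_ids)),
    longitude = seq(-100, 100, length.out = length(sample_ids)),
    stringsAsFactors = FALSE
  ), predictor_names = character(0))
}

# ---- independent oracles ---------------------------------------------------

# literal enumeration of the three dominance criteria, loop by loop
brute_force_dominance <- function(counts, biome, top_frac = 0.10,
                                  min_freq = 1 / 3, min_breadth_frac = 0.5) {
  n_phy <- nrow(counts)
  biomes <- sort(unique(biome))
  totals <- numeric(n_phy)
  for (i in seq_len(n_phy)) totals[i] <- sum(counts[i, ])
  cutoff <- ceiling(top_frac * n_phy)
  boundary <- sort(totals, decreasing = TRUE)[cutoff]
  abundant <- logical(n_phy)
  for (i in seq_len(n_phy)) abundant[i] <- totals[i] >= boundary
  dominant_in <- matrix(FALSE, n_phy, length(biomes))
  for (b in seq_along(biomes)) {
    cols <- which(biome == biomes[b])
    for (i in seq_len(n_phy)) {
      present <- 0
      for (j in cols) if (counts[i, j] > 0) present <- present + 1
      freq <- present / length(cols)
      dominant_in[i, b] <- abundant[i] && (freq >= min_freq)
    }
  }
  breadth <- rowSums(dominant_in)
  global <- breadth >= ceiling(min_breadth_frac * length(biomes))
  list(abundant = abundant, breadth = breadth, global = global)
}

# Spearman by explicit rank-then-Pearson, pair by pair
oracle_spearman <- function(mat) {
  n_phy <- nrow(mat)
  rho <- matrix(NA_real_, n_phy, n_phy)
  for (i in seq_len(n_phy)) {
    for (k in seq_len(n_phy)) {
      ri <- rank(mat[i, ])
      rk <- rank(mat[k, ])
      if (sd(ri) == 0 || sd(rk) == 0) next
      rho[i, k] <- sum((ri - mean(ri)) * (rk - mean(rk))) /
        sqrt(sum((ri - mean(ri))^2) * sum((rk - mean(rk))^2))
    }
  }
  diag(rho) <- 1
  rho
}

# closed-form first-order semi-partial on ranks: r_y(x.z)
oracle_semipartial_1 <- function(y, x, z) {
  ry <- rank(y); rx <- rank(x); rz <- rank(z)
  r_yx <- cor(ry, rx); r_yz <- cor(ry, rz); r_xz <- cor(rx, rz)
  (r_yx - r_yz * r_xz) / sqrt(1 - r_xz^2)
}

# full partial correlation with 2 controls from the precision matrix of ranks
oracle_partial_spatial <- function(y, x, lat, lon) {
  R <- cor(cbind(rank(y), rank(x), rank(lat), rank(lon)))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# planted 3-block random graph as a cooccurrence_network-shaped object
planted_block_network <- function(nodes_per_block = 15, p_in = 0.9,
                                  p_out = 0.05, seed = 1) {
  set.seed(seed)
  n <- 3 * nodes_per_block
  block <- rep(1:3, each = nodes_per_block)
  ids <- sprintf("N%02d", seq_len(n))
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (block[i] == block[j]) p_in else p_out
      if (runif(1) < p) {
        from <- c(from, ids[i]); to <- c(to, ids[j])
      }
    }
  }
  net <- structure(list(
    nodes = ids,
    edges = data.frame(from = from, to = to, rho = 0.8,
                       p = 1e-6, stringsAsFactors = FALSE),
    modules = setNames(character(0), character(0)),
    module_sizes = integer(0)
  ), class = "cooccurrence_network")
  list(net = net, truth = setNames(block, ids))
}
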