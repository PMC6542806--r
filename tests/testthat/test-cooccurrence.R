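test_that("monotone and antitone profile pairs reach rho = 1 and -1", {
  x <- c(1, 3, 4, 7, 9, 12, 15, 20, 21, 30)
  mat <- rbind(a = x, b = x^2 + 1, c = 100 - x)
  colnames(mat) <- paste0("s", 1:10)
  sp <- spearman_all_pairs(mat)
  expect_equal(sp$rho["a", "b"], 1)
  expect_equal(sp$rho["a", "c"], -1)
  expect_equal(sp$p["a", "b"], 0)
})

test_that("all-pairs Spearman matches explicit rank-then-Pearson", {
  for (seed in 1:5) {
    set.seed(seed)
    mat <- matrix(rnorm(5 * 20), 5, 20,
                  dimnames = list(paste0("t", 1:5), paste0("s", 1:20)))
    mat[sample(length(mat), 10)] <- 0  # induce ties
    sp <- spearman_all_pairs(mat)
    expect_equal(sp$rho, oracle_spearman(mat), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("constant profiles give NA correlations and never form edges", {
  mat <- rbind(a = c(1, 2, 3, 4, 5), b = rep(2, 5), c = c(5, 4, 3, 2, 1))
  colnames(mat) <- paste0("s", 1:5)
  sp <- spearman_all_pairs(mat)
  expect_true(all(is.na(sp$rho["b", c("a", "c")])))
  net <- build_network(sp$rho, sp$p, run_config(rho_threshold = -2, p_threshold = 1))
  expect_false(any(net$edges$from == "b" | net$edges$to == "b"))
})

test_that("edge rule is strict, positive-only, at rho > 0.40 and p < 0.01", {
  ids <- c("a", "b", "c", "d")
  rho <- diag(4); dimnames(rho) <- list(ids, ids)
  p <- matrix(1, 4, 4, dimnames = list(ids, ids))
  rho["a", "b"] <- rho["b", "a"] <- 0.41; p["a", "b"] <- p["b", "a"] <- 0.005
  rho["a", "c"] <- rho["c", "a"] <- 0.40; p["a", "c"] <- p["c", "a"] <- 0.001
  rho["b", "d"] <- rho["d", "b"] <- -0.9; p["b", "d"] <- p["d", "b"] <- 1e-6
  rho["c", "d"] <- rho["d", "c"] <- 0.6;  p["c", "d"] <- p["d", "c"] <- 0.01
  net <- build_network(rho, p)
  expect_identical(paste(net$edges$from, net$edges$to), "a b")
})

test_that("module detection recovers planted structure", {
  # two 6-cliques joined by a single bridge
  ids <- sprintf("n%02d", 1:12)
  cl <- function(members) t(combn(members, 2))
  ed <- rbind(cl(ids[1:6]), cl(ids[7:12]), c(ids[6], ids[7]))
  net <- structure(list(
    nodes = ids,
    edges = data.frame(from = ed[, 1], to = ed[, 2], rho = 0.9, p = 1e-5,
                       stringsAsFactors = FALSE),
    modules = setNames(character(0), character(0)), module_sizes = integer(0)
  ), class = "cooccurrence_network")
  net <- detect_modules(net, seed = 1)
  expect_equal(length(net$module_sizes), 2)
  expect_equal(length(unique(net$modules[ids[1:6]])), 1)
  expect_equal(length(unique(net$modules[ids[7:12]])), 1)

  # single triangle: one module of size 3
  tri <- structure(list(
    nodes = c("x", "y", "z"),
    edges = data.frame(from = c("x", "x", "y"), to = c("y", "z", "z"),
                       rho = 0.8, p = 1e-5, stringsAsFactors = FALSE),
    modules = setNames(character(0), character(0)), module_sizes = integer(0)
  ), class = "cooccurrence_network")
  tri <- detect_modules(tri, seed = 1)
  expect_identical(unname(tri$module_sizes), 3L)

  # planted 3-block graphs: exact recovery
  skip_if_not_installed("mclust")
  for (seed in 1:5) {
    pb <- planted_block_network(seed = seed)
    net <- detect_modules(pb$net, seed = seed)
    expect_equal(mclust::adjustedRandIndex(net$modules[pb$net$nodes], pb$truth), 1)
  }
})

test_that("empty networks degrade to singleton modules with a warning", {
  net <- structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(from = character(0), to = character(0),
                       rho = numeric(0), p = numeric(0)),
    modules = setNames(character(0), character(0)), module_sizes = integer(0)
  ), class = "cooccurrence_network")
  expect_warning(net <- detect_modules(net, seed = 1), "singleton")
  expect_equal(length(unique(net$modules)), 3)
  expect_equal(sum(net$module_sizes), 3)
})

test_that("network is invariant to sample permutation and monotone transforms", {
  set.seed(42)
  mat <- matrix(rlnorm(8 * 15), 8, 15,
                dimnames = list(paste0("t", 1:8), paste0("s", 1:15)))
  sp <- spearman_all_pairs(mat)
  net <- build_network(sp$rho, sp$p, run_config(rho_threshold = 0.2, p_threshold = 0.2))

  perm <- sample(15)
  sp2 <- spearman_all_pairs(mat[, perm])
  net2 <- build_network(sp2$rho, sp2$p, run_config(rho_threshold = 0.2, p_threshold = 0.2))
  expect_equal(net2$edges, net$edges, tolerance = 1e-12)

  # strictly monotone per-taxon transforms leave ranks, hence the network, fixed
  mat3 <- mat
  mat3[1, ] <- exp(mat3[1, ])
  mat3[2, ] <- mat3[2, ]^3
  sp3 <- spearman_all_pairs(mat3)
  net3 <- build_network(sp3$rho, sp3$p, run_config(rho_threshold = 0.2, p_threshold = 0.2))
  expect_equal(net3$edges, net$edges, tolerance = 1e-12)
})

test_that("z-scored module abundances honour the standardisation contract", {
  set.seed(10)
  rel <- matrix(runif(10 * 20), 10, 20,
                dimnames = list(paste0("t", 1:10), paste0("s", 1:20)))
  rel <- rbind(rel, t11 = rel["t1", ])          # perfectly correlated partner
  rel <- rbind(rel, t12 = rep(0.5, 20))         # zero-variance taxon
  sp <- spearman_all_pairs(rel[1:11, ])
  net <- build_network(sp$rho, sp$p, run_config(rho_threshold = -2, p_threshold = 1))
  net$nodes <- rownames(rel)
  net$modules <- setNames(c(paste0("M", 1:10), "M1", "M11"), rownames(rel))
  ca <- module_zscore_abundance(rel, net)

  z <- ca$zscores
  expect_true(all(abs(rowMeans(z[1:11, ])) < 1e-12))
  expect_true(all(abs(apply(z[1:11, ], 1, sd) - 1) < 1e-12))
  expect_true(all(z["t12", ] == 0))
  # single-member module score equals that member's z-score
  expect_equal(ca$scores[, "M2"], z["t2", ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # module of two perfectly correlated members equals either z-score
  expect_equal(ca$scores[, "M1"], z["t1", ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # module sizes partition the node set
  expect_equal(length(unlist(ca$modules)), nrow(rel))
})
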