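test_that("trait standardisation is plain scale-invariant division", {
  df <- data.frame(
    genome_id = c("g1", "g2", "g3"),
    group = c("a", "a", "b"),
    genome_size_mb = c(35, 40, 50),
    total_genes = c(10000, 12000, 9000),
    caz = c(40L, 0L, 90L),
    pep = c(10L, 20L, 30L),
    stringsAsFactors = FALSE
  )
  tt <- trait_table(df)
  f <- standardize_traits(tt)
  expect_equal(f["g1", "caz"], 0.004)
  expect_equal(f["g2", "caz"], 0)
  # doubling counts and totals leaves frequencies unchanged
  df2 <- df
  df2[, c("caz", "pep")] <- df2[, c("caz", "pep")] * 2L
  df2$total_genes <- df2$total_genes * 2L
  expect_equal(standardize_traits(trait_table(df2)), f, ignore_attr = TRUE)
  # genome-size denominator is the alternative convention
  f2 <- standardize_traits(tt, "genome_size_mb")
  expect_equal(f2["g3", "pep"], 30 / 50)
})

test_that("identical groups give zero differences and p = 1", {
  set.seed(1)
  block <- matrix(rpois(5 * 4, 30), 5, 4, dimnames = list(NULL, paste0("c", 1:4)))
  freqs <- rbind(block, block) / 1000
  rownames(freqs) <- paste0("g", 1:10)
  cmp <- compare_groups(freqs, groups = rep(c("d", "n"), each = 5),
                        n_permutations = 199, seed = 2)
  expect_equal(cmp$diff, rep(0, 4))
  expect_equal(cmp$p, rep(1, 4))
  expect_true(all(cmp$q >= cmp$p))
})

test_that("constant classes are flagged with p = 1", {
  freqs <- cbind(flat = rep(0.01, 8), vary = seq(0.01, 0.08, by = 0.01))
  rownames(freqs) <- paste0("g", 1:8)
  cmp <- compare_groups(freqs, groups = rep(c("d", "n"), each = 4),
                        n_permutations = 99, seed = 1)
  expect_true(cmp$constant[cmp$class == "flat"])
  expect_equal(cmp$p[cmp$class == "flat"], 1)
})

test_that("a planted two-fold enrichment is detected with high power", {
  hits <- vapply(1:40, function(rep) {
    g <- generate_trait_table(n_per_group = 10,
                              classes = c("enr", "null1", "null2"),
                              enriched = "enr", fold_change = 2,
                              base_class_mean = 50, seed = rep)
    f <- standardize_traits(g$traits, "genome_size_mb")
    # compare raw per-Mb frequencies; the enriched class doubles in group 1
    cmp <- compare_groups(f, n_permutations = 199, seed = rep)
    cmp$p[cmp$class == "enr"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("permutation p-values are calibrated under the null", {
  pvals <- vapply(1:200, function(rep) {
    g <- generate_trait_table(n_per_group = 10, classes = "c1",
                              enriched = character(0), fold_change = 1,
                              base_class_mean = 50, seed = rep + 1000)
    f <- standardize_traits(g$traits, "genome_size_mb")
    compare_groups(f, n_permutations = 199, seed = rep)$p
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.01)
  expect_lte(mean(pvals < 0.05), 0.10)
})

test_that("discriminative ranking puts a perfectly separating class first", {
  set.seed(5)
  n <- 16
  g <- rep(c("d", "n"), each = n / 2)
  freqs <- cbind(
    sep = ifelse(g == "d", 0.9, 0.1) + rnorm(n, 0, 0.01),
    noise1 = rnorm(n, 0.5, 0.1),
    noise2 = rnorm(n, 0.5, 0.1)
  )
  rownames(freqs) <- paste0("g", 1:n)
  rk <- rank_discriminative_traits(freqs, groups = g, n_permutations = 199, seed = 3)
  expect_identical(rk$class[1], "sep")
  # rank order is invariant under class-wise rescaling
  freqs2 <- freqs
  freqs2[, "noise1"] <- freqs2[, "noise1"] * 100
  rk2 <- rank_discriminative_traits(freqs2, groups = g, n_permutations = 199, seed = 3)
  expect_identical(rk$class, rk2$class)
})

test_that("exchangeable classes show no significant discrimination", {
  g <- generate_trait_table(n_per_group = 10, classes = paste0("c", 1:10),
                            enriched = character(0), fold_change = 1,
                            base_class_mean = 50, seed = 77)
  f <- standardize_traits(g$traits, "genome_size_mb")
  rk <- rank_discriminative_traits(f, n_permutations = 499, seed = 77)
  expect_equal(sum(rk$q < 0.05), 0)
})

test_that("group size and label validation are enforced", {
  freqs <- matrix(runif(12), 6, 2, dimnames = list(paste0("g", 1:6), c("a", "b")))
  expect_error(compare_groups(freqs, groups = c("d", "d", "n", "n", "n", "n")),
               "at least 3 genomes")
  expect_error(compare_groups(freqs, groups = rep("d", 6), labels = "d"),
               "two group labels")
})

test_that("trait tables from the generator validate and round-trip", {
  g <- generate_trait_table(n_per_group = 10, classes = paste0("c", 1:20),
                            enriched = paste0("c", 1:3), fold_change = 2, seed = 1)
  expect_equal(nrow(g$traits), 20)
  expect_identical(attr(g$traits, "classes"), paste0("c", 1:20))
  g2 <- generate_trait_table(n_per_group = 10, classes = paste0("c", 1:20),
                             enriched = paste0("c", 1:3), fold_change = 2, seed = 1)
  expect_identical(g$traits, g2$traits)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(g$traits, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_trait_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(g$traits),
               tolerance = 1e-12, ignore_attr = TRUE)
})
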