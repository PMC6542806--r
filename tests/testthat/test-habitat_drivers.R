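test_that("single-control semi-partial matches the closed form on ranks", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    z <- rnorm(n)
    x <- 0.6 * z + rnorm(n)
    y <- 0.5 * x - 0.3 * z + rnorm(n)
    X <- cbind(x = x, z = z)
    res <- semipartial_spearman(y, X)
    expect_equal(res$rho[res$predictor == "x"], oracle_semipartial_1(y, x, z),
                 tolerance = 1e-10)
    expect_equal(res$rho[res$predictor == "z"], oracle_semipartial_1(y, z, x),
                 tolerance = 1e-10)
  }
})

test_that("with controls rank-orthogonal to x the semi-partial is plain Spearman", {
  # ranks of z chosen with exactly zero correlation against ranks of x
  x <- c(10, 20, 30, 40)
  z <- c(2, 4, 1, 3)
  y <- c(5, 1, 4, 2)
  res <- semipartial_spearman(y, cbind(x = x, z = z))
  expect_equal(cor(rank(x), rank(z)), 0)
  expect_equal(res$rho[res$predictor == "x"],
               cor(rank(y), rank(x)), tolerance = 1e-12)
})

test_that("a strong monotone signal survives noise controls", {
  set.seed(7)
  n <- 200
  x <- runif(n)
  y <- exp(2 * x)                       # strictly increasing in x
  Z <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("z", 1:4)))
  res <- semipartial_spearman(y, cbind(x = x, Z))
  expect_gt(res$rho[res$predictor == "x"], 0.95)
  expect_lt(res$p[res$predictor == "x"], 1e-6)
})

test_that("rank-deficient controls raise an error naming the offenders", {
  set.seed(1)
  n <- 30
  x <- rnorm(n)
  z1 <- rnorm(n)
  X <- cbind(x = x, z1 = z1, z2 = z1)   # duplicated control, identical ranks
  expect_error(semipartial_spearman(rnorm(n), X), "rank-deficient.*z[12]")
})

test_that("spatial partial matches the precision-matrix oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    lat <- runif(n, -60, 60)
    lon <- runif(n, -150, 150)
    x <- 0.3 * lat + rnorm(n)
    y <- 0.2 * lat - 0.1 * lon + 0.4 * x + rnorm(n)
    got <- partial_spearman_spatial(y, x, lat, lon)
    expect_equal(got$rho, oracle_partial_spatial(y, x, lat, lon),
                 tolerance = 1e-10)
  }
})

test_that("spatial control removes a purely spatial association", {
  set.seed(3)
  n <- 300
  lat <- runif(n, -60, 60)
  # both variables driven by latitude alone (plus independent measurement noise,
  # without which the rank residuals are identically zero and rho undefined)
  y <- exp(lat / 30) * exp(rnorm(n, 0, 0.1))
  x <- lat^3 + rnorm(n, 0, 1000)
  lon <- rnorm(n)
  plain <- cor(rank(y), rank(x))
  got <- partial_spearman_spatial(y, x, lat, lon)
  expect_gt(plain, 0.99)
  expect_lt(abs(got$rho), 0.1)
  expect_error(partial_spearman_spatial(y, x, rep(1, n), lon), "latitude is constant")
})

test_that("independent coordinates leave the correlation essentially untouched", {
  set.seed(11)
  n <- 2000
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  lat <- runif(n, -60, 60)
  lon <- runif(n, -150, 150)
  got <- partial_spearman_spatial(y, x, lat, lon)
  expect_lt(abs(got$rho - cor(rank(y), rank(x))), 0.05)
})

test_that("semi-partial and partial correlations are rank-invariant", {
  set.seed(21)
  n <- 50
  x <- rnorm(n); z <- rnorm(n); y <- x + z + rnorm(n)
  lat <- runif(n, -40, 40); lon <- runif(n, -90, 90)
  a <- semipartial_spearman(y, cbind(x = x, z = z))
  b <- semipartial_spearman(exp(y), cbind(x = x^3 + 5, z = z))
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
  p1 <- partial_spearman_spatial(y, x, lat, lon)
  p2 <- partial_spearman_spatial(exp(y), x^3 + 5, lat, lon)
  expect_equal(p1$rho, p2$rho, tolerance = 1e-12)
})

test_that("ecosystem types are dummy-coded from biomes, strict on unknowns", {
  meta <- toy_meta(c("s1", "s2", "s3"),
                   c("temperate forest", "dry grassland", "shrubland"))
  eco <- encode_ecosystem(meta)
  expect_identical(unname(eco[, "forest"]), c(1L, 0L, 0L))
  expect_identical(unname(eco[, "grassland"]), c(0L, 1L, 0L))
  meta2 <- toy_meta("s1", "tundra")
  expect_error(encode_ecosystem(meta2), "tundra")
})

test_that("a linear response is recovered exactly and predicted perfectly", {
  set.seed(2)
  n <- 60
  X <- data.frame(aridity = runif(n), ph = rnorm(n, 6), uv = rnorm(n, 100, 10))
  y <- 2 - 3 * X$aridity
  scores <- cbind(M1 = y)
  fit <- fit_distribution_model(scores, X)
  # slope on standardised aridity = -3 * sd(aridity)
  expect_equal(unname(fit$fits$M1$coef["aridity"]), -3 * sd(X$aridity),
               tolerance = 1e-8)
  pe <- predict_and_evaluate(fit, scheme = "resubstitution")
  expect_equal(pe$evaluation$rho, 1, tolerance = 1e-12)
  pe2 <- predict_and_evaluate(fit, scheme = "kfold", seed = 5)
  expect_gt(pe2$evaluation$rho, 0.999)
  # determinism under a fixed seed
  pe3 <- predict_and_evaluate(fit, scheme = "kfold", seed = 5)
  expect_identical(pe2$site_predictions, pe3$site_predictions)
})

test_that("predictions clamp to the training range and flag degenerate grids", {
  set.seed(4)
  n <- 50
  X <- data.frame(aridity = runif(n))
  y <- 10 * X$aridity
  fit <- fit_distribution_model(cbind(M1 = y), X)
  far <- data.frame(aridity = c(-100, 100))
  pred <- predict(fit, far)
  expect_true(all(pred >= min(y) & pred <= max(y)))

  const_grid <- data.frame(aridity = rep(0.5, 4))
  expect_warning(pe <- predict_and_evaluate(fit, grid = const_grid),
                 "constant grid predictions")
  expect_identical(attr(pe$grid_predictions, "degenerate_modules"), "M1")
  expect_error(predict(fit, data.frame(ph = 1:3)), "missing grid predictor")
})

test_that("cluster-level driver table carries both correlation flavours", {
  d <- simulation_design(n_taxa = 400, n_dominant = 12, rng_seed = 2)
  meta <- generate_sites(d)
  com <- generate_community(d, meta)
  rel <- relative_abundance(com$table)
  dom <- com$truth$dominant_ids
  sp <- spearman_all_pairs(rel[dom, ])
  net <- detect_modules(build_network(sp$rho, sp$p), seed = 2)
  ca <- module_zscore_abundance(rel, net)
  drv <- cluster_drivers(ca, meta)
  expect_setequal(unique(drv$predictor),
                  c(attr(meta, "predictors"), "forest", "grassland"))
  expect_true(all(abs(drv$rho) <= 1, na.rm = TRUE))
  expect_true(all(drv$n <= nrow(meta)))
  expect_true(all(c("spatial_rho", "spatial_p") %in% colnames(drv)))
})
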