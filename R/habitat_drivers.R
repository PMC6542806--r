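# rank with average ties, NAs kept
rank_avg <- function(v) rank(v, ties.method = "average", na.last = "keep")

# residuals of y on (1, Z); errors on rank deficiency, naming columns
resid_on <- function(y, Z, what = "controls") {
  X <- cbind(`(intercept)` = 1, Z)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop2("rank-deficient %s: %s", what, paste(dropped, collapse = ", "))
  }
  qr.resid(qr_x, y)
}

#' Semi-partial (part) Spearman correlations of a response with predictors
#'
#' For each predictor x, the remaining columns of `X` act as controls Z. All
#' variables are rank-transformed (average ranks), the ranked x is
#' residualised on the ranked Z, and the semi-partial correlation is the
#' Pearson correlation between ranked y and that residual — the controls'
#' contribution is removed from the predictor only. Two-sided p-values use a
#' t statistic with n - k - 2 degrees of freedom (k = number of controls).
#' Rows with missing values in y, x or any control are dropped per pair.
#'
#' @param y numeric response (e.g. one module's abundance score).
#' @param X numeric matrix/data.frame of predictors with unique column names.
#' @return data.frame with columns predictor, rho, p, n, n_controls.
#' @export
semipartial_spearman <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop2("X must have unique column names")
  }
  out <- lapply(colnames(X), function(target) {
    xs <- X[, target]
    Z <- X[, setdiff(colnames(X), target), drop = FALSE]
    cc <- complete.cases(y, xs, Z)
    k <- ncol(Z)
    n <- sum(cc)
    if (n < k + 3) stop2("insufficient complete samples (%d) for %d controls", n, k)
    ry <- rank_avg(y[cc])
    rx <- rank_avg(xs[cc])
    rz <- apply(Z[cc, , drop = FALSE], 2, rank_avg)
    ex <- resid_on(rx, rz, what = "controls")
    if (sd(ex) == 0 || sd(ry) == 0) {
      return(data.frame(predictor = target, rho = NA_real_, p = NA_real_,
                        n = n, n_controls = k, stringsAsFactors = FALSE))
    }
    r <- cor(ry, ex)
    df <- n - k - 2
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    data.frame(predictor = target, rho = r,
               p = 2 * pt(abs(tstat), df = df, lower.tail = FALSE),
               n = n, n_controls = k, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Partial Spearman correlation controlling for latitude and longitude
#'
#' Full partial correlation: both y and x are rank-transformed, residualised
#' on the ranked coordinates, and the residuals correlated — the spatial
#' signal is removed from both variables. p from a t statistic with n - 4
#' degrees of freedom (2 controls).
#'
#' @param y,x numeric vectors.
#' @param lat,lon coordinate vectors (not constant).
#' @return list with `rho`, `p`, `n`.
#' @export
partial_spearman_spatial <- function(y, x, lat, lon) {
  cc <- complete.cases(y, x, lat, lon)
  n <- sum(cc)
  if (n < 6) stop2("need at least 6 complete samples")
  if (sd(lat[cc]) == 0) stop2("latitude is constant")
  if (sd(lon[cc]) == 0) stop2("longitude is constant")
  rz <- cbind(lat = rank_avg(lat[cc]), lon = rank_avg(lon[cc]))
  ey <- resid_on(rank_avg(y[cc]), rz, what = "spatial controls")
  ex <- resid_on(rank_avg(x[cc]), rz, what = "spatial controls")
  if (sd(ey) == 0 || sd(ex) == 0) return(list(rho = NA_real_, p = NA_real_, n = n))
  r <- cor(ey, ex)
  df <- n - 2 - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(rho = r, p = 2 * pt(abs(tstat), df = df, lower.tail = FALSE), n = n)
}

# default biome -> ecosystem-type mapping for the nine survey biomes;
# boreal is treated as forest (boreal forest/taiga)
default_biome_ecosystem <- function() {
  c("boreal" = "forest",
    "cold forest" = "forest",
    "dry forest" = "forest",
    "temperate forest" = "forest",
    "tropical forest" = "forest",
    "cold grassland" = "grassland",
    "dry grassland" = "grassland",
    "grassland" = "grassland",
    "shrubland" = "shrubland")
}

#' Dummy-code ecosystem types from biome labels
#'
#' Each requested ecosystem type becomes a 0/1 column: 1 when the sample's
#' biome maps to that type, 0 otherwise.
#'
#' @param meta a [sample_metadata] data.frame (or anything with a `biome`
#'   column).
#' @param types ecosystem types to encode (default forest and grassland, the
#'   survey's dominant types).
#' @param mapping named character vector biome -> ecosystem type.
#' @return integer matrix, samples x types.
#' @export
encode_ecosystem <- function(meta, types = c("forest", "grassland"),
                             mapping = default_biome_ecosystem()) {
  unmapped <- setdiff(unique(meta$biome), names(mapping))
  if (length(unmapped) > 0) {
    stop2("biome(s) with no ecosystem mapping: %s", paste(unmapped, collapse = ", "))
  }
  eco <- mapping[meta$biome]
  out <- vapply(types, function(tp) as.integer(eco == tp), integer(nrow(meta)))
  rownames(out) <- meta$sample_id
  out
}

#' Per-module environmental driver correlations
#'
#' For each module score and each predictor: the semi-partial Spearman
#' correlation with all other predictors as controls, and the spatially
#' controlled partial Spearman correlation (latitude/longitude removed from
#' both variables).
#'
#' @param ca a `cluster_abundance` from [module_zscore_abundance].
#' @param meta a [sample_metadata] data.frame aligned with the score rows.
#' @param predictors character vector of predictor column names in `meta`
#'   (defaults to the metadata's predictor attribute plus ecosystem flags).
#' @return data.frame of class `driver_correlations` with one row per
#'   (module, predictor).
#' @export
cluster_drivers <- function(ca, meta, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- c(attr(meta, "predictors"), attr(meta, "ecosystem_flags"))
  }
  if (!identical(rownames(ca$scores), meta$sample_id)) {
    stop2("cluster scores and metadata are not aligned")
  }
  X <- as.matrix(as.data.frame(meta)[, predictors, drop = FALSE])
  out <- lapply(colnames(ca$scores), function(m) {
    y <- ca$scores[, m]
    sp <- semipartial_spearman(y, X)
    spatial <- lapply(predictors, function(pr) {
      partial_spearman_spatial(y, X[, pr], meta$latitude, meta$longitude)
    })
    sp$module <- m
    sp$spatial_rho <- vapply(spatial, `[[`, numeric(1), "rho")
    sp$spatial_p <- vapply(spatial, `[[`, numeric(1), "p")
    sp[, c("module", "predictor", "rho", "p", "n", "n_controls",
           "spatial_rho", "spatial_p")]
  })
  res <- do.call(rbind, out)
  class(res) <- c("driver_correlations", "data.frame")
  res
}

#' Fit per-module distribution models on environmental predictors
#'
#' Default is a linear model on standardised predictors (transparent and
#' stable at survey scale); a tree ensemble (ranger) is available as an
#' alternative. Training predictor means/SDs and observed score ranges are
#' stored so later predictions can be standardised identically and clamped.
#'
#' @param scores a `cluster_abundance` or a samples x modules numeric matrix.
#' @param X data.frame/matrix of predictors (complete rows required).
#' @param model `"linear"` or `"tree"`.
#' @param seed integer seed (tree model; fold draws downstream).
#' @return object of class `distribution_model`.
#' @export
fit_distribution_model <- function(scores, X, model = c("linear", "tree"),
                                   seed = 1L) {
  model <- match.arg(model)
  if (inherits(scores, "cluster_abundance")) scores <- scores$scores
  scores <- as.matrix(scores)
  X <- as.matrix(X)
  if (anyNA(X)) stop2("predictors must be complete for model fitting")
  if (nrow(X) != nrow(scores)) stop2("scores and predictors disagree on samples")
  if (nrow(X) < 2 * ncol(X) && model == "linear") {
    warning(sprintf("only %d samples for %d predictors", nrow(X), ncol(X)),
            call. = FALSE)
  }
  centers <- colMeans(X)
  scales <- apply(X, 2, sd)
  scales[scales == 0] <- 1
  Xs <- scale(X, center = centers, scale = scales)
  fits <- lapply(colnames(scores), function(m) {
    y <- scores[, m]
    if (model == "linear") {
      Xd <- cbind(`(intercept)` = 1, Xs)
      qr_x <- qr(Xd)
      if (qr_x$rank < ncol(Xd)) {
        dropped <- colnames(Xd)[qr_x$pivot[(qr_x$rank + 1):ncol(Xd)]]
        stop2("rank-deficient design: %s", paste(dropped, collapse = ", "))
      }
      list(coef = qr.coef(qr_x, y), range = range(y))
    } else {
      if (!requireNamespace("ranger", quietly = TRUE)) {
        stop2("tree model requires the ranger package")
      }
      dat <- data.frame(.y = y, Xs, check.names = FALSE)
      fit <- ranger::ranger(.y ~ ., data = dat, num.trees = 500, seed = seed)
      list(fit = fit, range = range(y))
    }
  })
  names(fits) <- colnames(scores)
  structure(list(model = model, fits = fits, centers = centers,
                 scales = scales, predictors = colnames(X),
                 X = X, scores = scores, seed = as.integer(seed)),
            class = "distribution_model")
}

predict_one <- function(fit_obj, model, Xs) {
  pred <- if (model == "linear") {
    drop(cbind(1, Xs) %*% fit_obj$coef)
  } else {
    predict(fit_obj$fit, data = data.frame(Xs, check.names = FALSE))$predictions
  }
  pmin(pmax(pred, fit_obj$range[1]), fit_obj$range[2])
}

#' Predict module abundances on new predictor data
#'
#' Predictions are clamped to each module's training score range, preventing
#' wild extrapolation beyond surveyed conditions.
#'
#' @param object a `distribution_model`.
#' @param newdata data.frame/matrix containing the training predictors.
#' @param ... unused.
#' @return matrix, rows of `newdata` x modules.
#' @export
predict.distribution_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$predictors, colnames(newdata))
  if (length(miss) > 0) stop2("missing grid predictor(s): %s", paste(miss, collapse = ", "))
  newdata <- as.matrix(newdata[, object$predictors, drop = FALSE])
  Xs <- scale(newdata, center = object$centers, scale = object$scales)
  out <- vapply(names(object$fits), function(m) {
    predict_one(object$fits[[m]], object$model, Xs)
  }, numeric(nrow(newdata)))
  if (is.null(dim(out))) {
    out <- matrix(out, nrow = nrow(newdata),
                  dimnames = list(rownames(newdata), names(object$fits)))
  }
  out
}

#' Predict over a grid and evaluate predicted vs observed module abundance
#'
#' Evaluation is a Spearman correlation between predicted and observed scores
#' at the training sites, either by resubstitution (fit and evaluate on all
#' sites) or by k-fold cross-validation (out-of-fold predictions; default
#' k = 10). Modules whose predictions are constant are flagged degenerate and
#' get NA correlations.
#'
#' @param model a fitted `distribution_model`.
#' @param grid optional data.frame of grid cells carrying the training
#'   predictors (and typically coordinates); NULL skips grid prediction.
#' @param obs observed scores: `cluster_abundance` or matrix aligned with the
#'   model's training rows.
#' @param scheme `"resubstitution"` or `"kfold"`.
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @return list of class `prediction_grid` with `evaluation` (data.frame:
#'   module, rho, p, n, scheme, degenerate), `site_predictions`, and
#'   `grid_predictions` (NULL without a grid).
#' @export
predict_and_evaluate <- function(model, grid = NULL, obs = model$scores,
                                 scheme = c("resubstitution", "kfold"),
                                 k = 10L, seed = model$seed) {
  scheme <- match.arg(scheme)
  if (inherits(obs, "cluster_abundance")) obs <- obs$scores
  obs <- as.matrix(obs)
  n <- nrow(model$X)
  if (scheme == "resubstitution") {
    pred <- predict(model, model$X)
  } else {
    folds <- with_rng_seed(seed, sample(rep_len(seq_len(k), n)))
    pred <- matrix(NA_real_, n, ncol(obs), dimnames = dimnames(obs))
    for (f in seq_len(k)) {
      test <- folds == f
      fit_f <- fit_distribution_model(obs[!test, , drop = FALSE],
                                      model$X[!test, , drop = FALSE],
                                      model = model$model, seed = seed)
      pred[test, ] <- predict(fit_f, model$X[test, , drop = FALSE])
    }
  }
  evaluation <- do.call(rbind, lapply(colnames(obs), function(m) {
    degenerate <- sd(pred[, m]) == 0 || sd(obs[, m]) == 0
    if (degenerate) {
      rho <- NA_real_; pv <- NA_real_
    } else {
      ct <- suppressWarnings(
        stats::cor.test(pred[, m], obs[, m], method = "spearman", exact = FALSE))
      rho <- unname(ct$estimate); pv <- ct$p.value
    }
    data.frame(module = m, rho = rho, p = pv, n = n, scheme = scheme,
               degenerate = degenerate, stringsAsFactors = FALSE)
  }))
  grid_pred <- if (!is.null(grid)) {
    gp <- predict(model, grid)
    out <- cbind(as.data.frame(grid), gp)
    degen <- colnames(gp)[apply(gp, 2, sd) == 0]
    if (length(degen) > 0) {
      warning(sprintf("constant grid predictions for module(s): %s",
                      paste(degen, collapse = ", ")), call. = FALSE)
    }
    attr(out, "degenerate_modules") <- degen
    out
  } else NULL
  structure(list(evaluation = evaluation, site_predictions = pred,
                 grid_predictions = grid_pred),
            class = "prediction_grid")
}
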