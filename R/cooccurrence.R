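#' All-pairs Spearman correlations between phylotypes
#'
#' Ranks each phylotype's abundance profile across samples (average ranks for
#' ties) and computes all pairwise Pearson correlations of the ranks, i.e.
#' Spearman's rho. Two-sided p-values come from the t-distribution
#' approximation with n - 2 degrees of freedom. Phylotypes with zero variance
#' get NA against every partner (such pairs can never form an edge).
#'
#' @param rel numeric matrix, phylotypes x samples (typically relative
#'   abundances of the dominant set).
#' @return list with symmetric matrices `rho` (unit diagonal) and `p`
#'   (diagonal NA).
#' @export
spearman_all_pairs <- function(rel) {
  n <- ncol(rel)
  if (n < 4) stop2("need at least 4 samples for meaningful p-values")
  ranked <- t(apply(rel, 1, rank, ties.method = "average"))
  sds <- apply(ranked, 1, sd)
  rho <- suppressWarnings(cor(t(ranked), method = "pearson"))
  rho[sds == 0, ] <- NA_real_
  rho[, sds == 0] <- NA_real_
  diag(rho) <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.na(rho) & abs(rho) >= 1] <- 0
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho)
  list(rho = rho, p = p)
}

#' Threshold a correlation matrix into a co-occurrence network
#'
#' Keeps only robust positive co-occurrences: pairs with rho strictly greater
#' than `cfg$rho_threshold` (and > 0) and p strictly below `cfg$p_threshold`.
#' NA pairs are excluded. Modules are left unassigned.
#'
#' @param rho,p symmetric matrices from [spearman_all_pairs].
#' @param cfg a [run_config].
#' @return a `cooccurrence_network` object (nodes, edge data.frame with
#'   columns from/to/rho/p, empty modules).
#' @export
build_network <- function(rho, p, cfg = run_config()) {
  if (!isTRUE(all.equal(dim(rho), dim(p))) ||
      !identical(rownames(rho), rownames(p))) {
    stop2("rho and p matrices must be aligned")
  }
  nodes <- rownames(rho)
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  pv <- p[idx]
  if (cfg$p_adjust_edges) pv <- p.adjust(pv, method = "BH")
  keep <- !is.na(r) & !is.na(pv) & r > cfg$rho_threshold & r > 0 & pv < cfg$p_threshold
  edges <- data.frame(
    from = nodes[idx[keep, 1]],
    to = nodes[idx[keep, 2]],
    rho = r[keep],
    p = pv[keep],
    stringsAsFactors = FALSE
  )
  dtx_log("network: %d of %d candidate pairs kept as edges over %d nodes",
          nrow(edges), length(r), length(nodes))
  structure(list(nodes = nodes, edges = edges,
                 modules = setNames(character(0), character(0)),
                 module_sizes = integer(0)),
            class = "cooccurrence_network")
}

#' Detect ecological clusters (modules) by modularity optimisation
#'
#' Runs greedy multilevel (Louvain) modularity optimisation on the weighted
#' co-occurrence network, the default method family of common network GUIs.
#' Modules are relabelled `M1`, `M2`, ... in decreasing size order (ties
#' broken by the smallest member index); isolated nodes end up as singleton
#' modules. Deterministic for a given seed.
#'
#' @param net a `cooccurrence_network` from [build_network].
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer RNG seed.
#' @return the network with `modules` and `module_sizes` filled in.
#' @export
detect_modules <- function(net, resolution = 1.0, seed = 1L) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  if (nrow(net$edges) == 0) {
    warning("empty edge set: every node becomes a singleton module", call. = FALSE)
    membership <- seq_along(net$nodes)
    names(membership) <- net$nodes
  } else {
    igraph::E(g)$weight <- net$edges$rho
    comm <- with_rng_seed(seed,
      igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                              resolution = resolution))
    membership <- igraph::membership(comm)
  }
  # relabel by decreasing size; tie-break on smallest member position
  sizes <- table(membership)
  first_member <- tapply(seq_along(membership), membership, min)
  ord <- order(-as.integer(sizes), first_member[names(sizes)])
  relabel <- setNames(paste0("M", seq_along(ord)), names(sizes)[ord])
  modules <- setNames(unname(relabel[as.character(membership)]), names(membership))
  net$modules <- modules[net$nodes]
  net$module_sizes <- sort(table(net$modules), decreasing = TRUE)
  net$module_sizes <- setNames(as.integer(net$module_sizes), names(net$module_sizes))
  dtx_log("modules: %d detected; largest three hold %d of %d nodes",
          length(net$module_sizes),
          sum(utils::head(sort(net$module_sizes, decreasing = TRUE), 3)),
          length(net$nodes))
  net
}

#' Standardised (z-score) cluster abundances
#'
#' Standardises each phylotype's relative abundance across samples to mean 0
#' and SD 1 (sample SD, n - 1; zero-variance phylotypes get z = 0), then
#' averages the z-scores of each module's members, giving one abundance score
#' per module per sample.
#'
#' @param rel numeric matrix, phylotypes x samples; rows must cover the
#'   network's nodes.
#' @param net a `cooccurrence_network` with modules assigned.
#' @return object of class `cluster_abundance`: list with `scores` (samples x
#'   modules matrix), `modules` (member list) and `zscores` (phylotypes x
#'   samples).
#' @export
module_zscore_abundance <- function(rel, net) {
  if (length(net$modules) == 0) stop2("modules not assigned; run detect_modules()")
  miss <- setdiff(net$nodes, rownames(rel))
  if (length(miss) > 0) {
    stop2("abundance matrix lacks node(s): %s", paste(utils::head(miss, 5), collapse = ", "))
  }
  x <- rel[net$nodes, , drop = FALSE]
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  z <- sweep(x, 1, mu, "-")
  z <- sweep(z, 1, ifelse(s == 0, 1, s), "/")
  z[s == 0, ] <- 0
  members <- split(net$nodes, net$modules[net$nodes])
  scores <- vapply(members, function(m) colMeans(z[m, , drop = FALSE]),
                   numeric(ncol(z)))
  if (is.null(dim(scores))) {
    scores <- matrix(scores, ncol = length(members),
                     dimnames = list(colnames(z), names(members)))
  }
  rownames(scores) <- colnames(z)
  structure(list(scores = scores, modules = members, zscores = z),
            class = "cluster_abundance")
}
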