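#' Read a genome trait table
#'
#' TSV with one row per genome: columns `genome_id`, `group`,
#' `genome_size_mb`, `total_genes`, then one column per gene class.
#'
#' @param path TSV file path.
#' @return data.frame of class `trait_table` with attribute `"classes"`.
#' @export
read_trait_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  required <- c("genome_id", "group", "genome_size_mb", "total_genes")
  miss <- setdiff(required, colnames(df))
  if (length(miss) > 0) stop2("missing trait column(s): %s", paste(miss, collapse = ", "))
  trait_table(df)
}

#' Validate a genome trait table
#' @param df data.frame as in [read_trait_table].
#' @return the validated `trait_table`.
#' @export
trait_table <- function(df) {
  classes <- setdiff(colnames(df), c("genome_id", "group", "genome_size_mb",
                                     "total_genes"))
  if (length(classes) == 0) stop2("no gene-class columns found")
  if (anyDuplicated(df$genome_id)) stop2("duplicate genome IDs")
  if (any(df$genome_size_mb <= 0)) stop2("genome sizes must be positive")
  if (any(df$total_genes <= 0)) stop2("total gene counts must be positive")
  cmat <- as.matrix(df[, classes, drop = FALSE])
  if (any(cmat < 0) || any(cmat != round(cmat))) {
    stop2("gene-class counts must be non-negative integers")
  }
  if (any(df$total_genes < apply(cmat, 1, max))) {
    stop2("total_genes must be at least the largest class count")
  }
  attr(df, "classes") <- classes
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Standardise gene-class counts to genome size
#'
#' Converts raw class counts to per-genome frequencies, dividing by the total
#' gene count (default) or the genome size in Mb.
#'
#' @param traits a `trait_table`.
#' @param denominator `"total_genes"` or `"genome_size_mb"`.
#' @return numeric matrix, genomes x classes, with `group` attribute.
#' @export
standardize_traits <- function(traits, denominator = c("total_genes",
                                                       "genome_size_mb")) {
  denominator <- match.arg(denominator)
  den <- traits[[denominator]]
  if (any(den <= 0)) stop2("denominator '%s' must be positive", denominator)
  classes <- attr(traits, "classes")
  freqs <- as.matrix(traits[, classes, drop = FALSE]) / den
  rownames(freqs) <- traits$genome_id
  attr(freqs, "group") <- traits$group
  freqs
}

#' Permutation test for group differences in standardised trait frequencies
#'
#' For each gene class, the statistic is the difference in group mean
#' frequency (first label minus second). The null is generated by permuting
#' group labels; the two-sided p-value is
#' `(1 + #{|perm| >= |obs|}) / (1 + n_permutations)`, and Benjamini-Hochberg
#' adjustment is applied across classes. Classes constant over all genomes
#' are flagged and given p = 1.
#'
#' @param freqs standardised frequency matrix from [standardize_traits].
#' @param groups group label per genome (defaults to the matrix's group
#'   attribute).
#' @param labels length-2 character: the two groups to compare.
#' @param n_permutations number of label permutations.
#' @param seed integer seed.
#' @return data.frame of class `trait_comparison`: per class the group means,
#'   mean difference, permutation p, BH q, constant flag; group sizes in
#'   attributes.
#' @export
compare_groups <- function(freqs, groups = attr(freqs, "group"),
                           labels = NULL, n_permutations = 999L, seed = 1L) {
  groups <- as.character(groups)
  if (is.null(labels)) labels <- unique(groups)[1:2]
  if (length(labels) != 2) stop2("exactly two group labels are required")
  sel <- groups %in% labels
  f <- freqs[sel, , drop = FALSE]
  g <- groups[sel]
  n1 <- sum(g == labels[1]); n2 <- sum(g == labels[2])
  if (n1 < 3 || n2 < 3) stop2("each group needs at least 3 genomes (got %d, %d)", n1, n2)
  n <- n1 + n2
  w <- ifelse(g == labels[1], 1 / n1, -1 / n2)
  obs <- drop(crossprod(w, f))
  B <- as.integer(n_permutations)
  perm_w <- with_rng_seed(seed, {
    vapply(seq_len(B), function(b) w[sample.int(n)], numeric(n))
  })
  perm_stats <- crossprod(perm_w, f)  # B x classes
  # tolerance guards float-equal permuted statistics (e.g. relabelled copies)
  exceed <- colSums(sweep(abs(perm_stats), 2, abs(obs) - 1e-15, ">="))
  p <- (1 + exceed) / (1 + B)
  constant <- apply(f, 2, function(v) length(unique(v)) == 1)
  p[constant] <- 1
  res <- data.frame(
    class = colnames(f),
    mean_group1 = drop(crossprod(as.numeric(g == labels[1]) / n1, f)),
    mean_group2 = drop(crossprod(as.numeric(g == labels[2]) / n2, f)),
    diff = unname(obs),
    p = unname(p),
    q = unname(p.adjust(p, method = "BH")),
    constant = unname(constant),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "groups") <- labels
  attr(res, "n_per_group") <- c(n1, n2)
  attr(res, "n_permutations") <- B
  class(res) <- c("trait_comparison", "data.frame")
  res
}

#' Rank gene classes by how strongly they discriminate two groups
#'
#' Transparent alternative to tree-ensemble importance at small sample size:
#' classes are ranked by the absolute standardised mean difference (Cohen's d
#' with pooled SD) of their frequencies, with permutation p-values from
#' [compare_groups] attached.
#'
#' @inheritParams compare_groups
#' @return data.frame ordered by decreasing |d|: class, cohens_d, p, q, rank.
#' @export
rank_discriminative_traits <- function(freqs, groups = attr(freqs, "group"),
                                       labels = NULL, n_permutations = 999L,
                                       seed = 1L) {
  groups <- as.character(groups)
  if (is.null(labels)) labels <- unique(groups)[1:2]
  cmp <- compare_groups(freqs, groups, labels, n_permutations, seed)
  sel <- groups %in% labels
  f <- freqs[sel, , drop = FALSE]
  g <- groups[sel]
  n1 <- sum(g == labels[1]); n2 <- sum(g == labels[2])
  v1 <- apply(f[g == labels[1], , drop = FALSE], 2, var)
  v2 <- apply(f[g == labels[2], , drop = FALSE], 2, var)
  pooled_sd <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- ifelse(pooled_sd == 0, 0, cmp$diff / pooled_sd)
  out <- data.frame(class = cmp$class, cohens_d = unname(d),
                    p = cmp$p, q = cmp$q, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$cohens_d), out$class), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
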