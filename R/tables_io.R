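#' Construct and validate a phylotype count table
#'
#' The canonical container for amplicon survey counts: a non-negative integer
#' matrix with phylotypes as rows and samples as columns. Samples with zero
#' total reads are rejected (they carry no compositional information).
#'
#' @param counts numeric matrix of non-negative integers, phylotypes x samples.
#' @param phylotype_ids,sample_ids optional character vectors of unique IDs;
#'   default to the dimnames of `counts`.
#' @return an object of class `phylotype_table` (a matrix with dimnames).
#' @export
phylotype_table <- function(counts, phylotype_ids = rownames(counts),
                            sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(phylotype_ids) || is.null(sample_ids)) {
    stop2("phylotype and sample IDs are required")
  }
  rownames(counts) <- as.character(phylotype_ids)
  colnames(counts) <- as.character(sample_ids)
  validate_phylotype_table(counts)
  structure(counts, class = c("phylotype_table", class(counts)))
}

validate_phylotype_table <- function(counts) {
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop2("need at least 2 phylotypes and 2 samples (got %d x %d)",
          nrow(counts), ncol(counts))
  }
  dup_r <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_r) > 0) {
    stop2("duplicate phylotype ID(s): %s", paste(unique(dup_r), collapse = ", "))
  }
  dup_c <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_c) > 0) {
    stop2("duplicate sample ID(s): %s", paste(unique(dup_c), collapse = ", "))
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop2("counts must be numeric with no missing values")
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop2("negative or non-integer count at row '%s', column '%s'",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  }
  zero <- colnames(counts)[colSums(counts) == 0]
  if (length(zero) > 0) {
    stop2("sample(s) with zero total reads: %s", paste(zero, collapse = ", "))
  }
  invisible(counts)
}

#' Read a phylotype table from a tab-separated file
#'
#' Expects a header row and a first column of IDs (classic BIOM-style TSV
#' export). Orientation is never guessed: say explicitly whether rows are
#' phylotypes or samples; the returned table is always phylotypes x samples.
#'
#' @param path path to a TSV file.
#' @param orientation `"phylotypes"` if rows are phylotypes (default),
#'   `"samples"` if rows are samples.
#' @return a [phylotype_table].
#' @export
read_phylotype_table <- function(path, orientation = c("phylotypes", "samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop2("file not found: %s", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  mat <- raw[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop2("non-numeric cell at row '%s', column '%s'",
            ids[bad %||% 1], colnames(mat)[j])
    }
  }
  mat <- as.matrix(mat)
  rownames(mat) <- ids
  if (orientation == "samples") mat <- t(mat)
  phylotype_table(mat)
}

#' Read per-sample metadata
#'
#' Reads a CSV or TSV (chosen by file extension) with required columns
#' `sample_id`, `biome`, `latitude`, `longitude` plus the named environmental
#' predictors. Predictors may contain missing values (excluded pairwise by the
#' correlation routines); biome and coordinates may not.
#'
#' @param path path to a CSV/TSV file.
#' @param predictor_names character vector of predictor column names to load.
#' @return a data.frame with one row per sample and attribute `"predictors"`.
#' @export
read_metadata <- function(path, predictor_names) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  required <- c("sample_id", "biome", "latitude", "longitude")
  miss <- setdiff(required, colnames(df))
  if (length(miss) > 0) stop2("missing metadata column(s): %s", paste(miss, collapse = ", "))
  miss_p <- setdiff(predictor_names, colnames(df))
  if (length(miss_p) > 0) {
    stop2("missing predictor column(s): %s", paste(miss_p, collapse = ", "))
  }
  sample_metadata(df, predictor_names)
}

#' Construct and validate a sample metadata table
#'
#' @param df data.frame with columns `sample_id`, `biome`, `latitude`,
#'   `longitude` and the predictors.
#' @param predictor_names which columns are environmental predictors.
#' @return validated data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df, predictor_names) {
  if (anyDuplicated(df$sample_id)) {
    stop2("duplicate sample_id(s): %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (anyDuplicated(predictor_names)) stop2("predictor names must be unique")
  if (anyNA(df$biome) || any(df$biome == "")) stop2("biome labels may not be missing")
  if (anyNA(df$latitude) || any(df$latitude < -90 | df$latitude > 90)) {
    stop2("latitude out of [-90, 90] (or missing)")
  }
  if (anyNA(df$longitude) || any(df$longitude < -180 | df$longitude > 180)) {
    stop2("longitude out of [-180, 180] (or missing)")
  }
  flag_cols <- intersect(c("forest", "grassland"), colnames(df))
  flag_cols <- setdiff(flag_cols, predictor_names)
  for (fc in flag_cols) {
    if (!all(df[[fc]] %in% c(0, 1))) stop2("ecosystem flag '%s' must be 0/1", fc)
  }
  df$sample_id <- as.character(df$sample_id)
  attr(df, "predictors") <- predictor_names
  attr(df, "ecosystem_flags") <- flag_cols
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Align a phylotype table with its sample metadata
#'
#' Brings both objects to an identical, identically ordered sample set.
#' `strict` errors on any mismatch; `intersect` drops unmatched samples on
#' either side and logs the drops.
#'
#' @param table a [phylotype_table].
#' @param meta a [sample_metadata] data.frame.
#' @param policy `"strict"` or `"intersect"`.
#' @return list with elements `table` and `meta`.
#' @export
align_table_metadata <- function(table, meta, policy = c("strict", "intersect")) {
  policy <- match.arg(policy)
  ts <- colnames(table)
  ms <- meta$sample_id
  if (policy == "strict") {
    unmatched <- c(setdiff(ts, ms), setdiff(ms, ts))
    if (length(unmatched) > 0) {
      stop2("sample sets differ; unmatched: %s", paste(unmatched, collapse = ", "))
    }
    common <- ts
  } else {
    common <- intersect(ts, ms)
    if (length(common) == 0) stop2("no samples shared between table and metadata")
    dropped <- c(setdiff(ts, common), setdiff(ms, common))
    if (length(dropped) > 0) {
      dtx_log("alignment dropped %d of %d sample(s): %s",
              length(dropped), length(union(ts, ms)),
              paste(dropped, collapse = ", "))
    }
  }
  tab <- table[, common, drop = FALSE]
  class(tab) <- class(table)
  meta2 <- meta[match(common, meta$sample_id), , drop = FALSE]
  rownames(meta2) <- NULL
  attr(meta2, "predictors") <- attr(meta, "predictors")
  attr(meta2, "ecosystem_flags") <- attr(meta, "ecosystem_flags")
  class(meta2) <- class(meta)
  list(table = phylotype_table(tab), meta = meta2)
}

#' Analysis configuration
#'
#' Bundles the pipeline thresholds. Defaults implement the dominance
#' definition used throughout: top 10% of phylotypes by total read share,
#' presence in at least one third of a biome's samples, and dominance in at
#' least half of the biomes; network edges require Spearman rho > 0.40 at
#' p < 0.01 (positive correlations only).
#'
#' @param top_abundance_fraction fraction of phylotypes counted as "abundant".
#' @param min_biome_frequency minimum within-biome occurrence frequency.
#' @param min_breadth_fraction minimum fraction of biomes where a phylotype
#'   must be dominant to count as globally dominant.
#' @param rho_threshold,p_threshold co-occurrence edge rule (strict `>`/`<`).
#' @param module_resolution Louvain resolution parameter.
#' @param n_permutations permutations for the trait tests.
#' @param rng_seed integer seed for all seeded steps.
#' @param abundance_scope rank phylotype abundance on pooled reads across all
#'   samples (`"global"`, default) or within each biome (`"biome"`).
#' @param rarefy_to optional depth to rarefy each sample to before dominance
#'   ranking (sensitivity analysis; requires the vegan package).
#' @param p_adjust_edges apply Benjamini-Hochberg correction to edge p-values
#'   before thresholding (sensitivity analysis; default FALSE, raw p).
#' @return a list of class `run_config`.
#' @export
run_config <- function(top_abundance_fraction = 0.10,
                       min_biome_frequency = 1 / 3,
                       min_breadth_fraction = 0.5,
                       rho_threshold = 0.40,
                       p_threshold = 0.01,
                       module_resolution = 1.0,
                       n_permutations = 999L,
                       rng_seed = 1L,
                       abundance_scope = c("global", "biome"),
                       rarefy_to = NULL,
                       p_adjust_edges = FALSE) {
  abundance_scope <- match.arg(abundance_scope)
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x <= 1
  if (!in01(top_abundance_fraction)) stop2("top_abundance_fraction must be in (0, 1]")
  if (!in01(min_biome_frequency)) stop2("min_biome_frequency must be in (0, 1]")
  if (!in01(min_breadth_fraction)) stop2("min_breadth_fraction must be in (0, 1]")
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop2("p_threshold must be in (0, 1]")
  }
  if (!is.numeric(module_resolution) || module_resolution <= 0) {
    stop2("module_resolution must be > 0")
  }
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    stop2("n_permutations must be a positive integer")
  }
  structure(list(
    top_abundance_fraction = top_abundance_fraction,
    min_biome_frequency = min_biome_frequency,
    min_breadth_fraction = min_breadth_fraction,
    rho_threshold = rho_threshold,
    p_threshold = p_threshold,
    module_resolution = module_resolution,
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed),
    abundance_scope = abundance_scope,
    rarefy_to = rarefy_to,
    p_adjust_edges = isTRUE(p_adjust_edges)
  ), class = "run_config")
}

#' Write a pipeline result to disk
#'
#' Dominance results, driver correlations, trait comparisons and cluster
#' abundances are written as TSV; co-occurrence networks as JSON node/edge
#' lists. Floating-point values are serialized with 15 significant digits so
#' that reading the file back reconstructs an equal object.
#'
#' @param obj a pipeline result object.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(obj, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(obj, "cooccurrence_network")) {
    if (format != "json") stop2("cooccurrence_network is written as JSON")
    payload <- list(
      nodes = obj$nodes,
      edges = obj$edges,
      modules = as.list(obj$modules),
      module_sizes = as.list(obj$module_sizes)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null", na = "null")
    return(invisible(path))
  }
  if (inherits(obj, "cluster_abundance")) {
    df <- data.frame(sample_id = rownames(obj$scores), obj$scores,
                     check.names = FALSE, stringsAsFactors = FALSE)
    obj <- df
  }
  if (!is.data.frame(obj)) {
    stop2("unsupported result type: %s", paste(class(obj), collapse = "/"))
  }
  if (format != "tsv") stop2("tabular results are written as TSV")
  out <- obj
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV result written by [write_results]
#'
#' @param path file path.
#' @return a data.frame with numeric columns restored.
#' @export
read_results_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(ifelse(v == "NA", NA, v)))
      if (!anyNA(num[v != "NA"])) df[[j]] <- num
    } else if (is.logical(v) || is.integer(v)) {
      df[[j]] <- v
    }
  }
  df
}

#' Read back a co-occurrence network written by [write_results]
#'
#' @param path JSON file path.
#' @return a `cooccurrence_network` object.
#' @export
read_cooccurrence_network <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as.data.frame(js$edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        rho = numeric(), p = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(
    nodes = as.character(js$nodes),
    edges = edges,
    modules = unlist(js$modules) %||% setNames(character(0), character(0)),
    module_sizes = unlist(js$module_sizes) %||% integer(0)
  ), class = "cooccurrence_network")
}

#' Check a FASTA of representative sequences against a phylotype table
#'
#' Warns (does not error) when sequence IDs and table row IDs disagree,
#' mirroring the usual loose coupling between a representative-sequence file
#' and its count table.
#'
#' @param fasta_path path to a FASTA file.
#' @param table a [phylotype_table].
#' @return invisibly, the character vector of shared IDs.
#' @export
check_fasta_ids <- function(fasta_path, table) {
  lines <- readLines(fasta_path)
  ids <- sub("^>(\\S+).*$", "\\1", lines[startsWith(lines, ">")])
  only_fa <- setdiff(ids, rownames(table))
  only_tab <- setdiff(rownames(table), ids)
  if (length(only_fa) > 0) {
    warning(sprintf("%d FASTA ID(s) absent from table (e.g. %s)",
                    length(only_fa), only_fa[1]), call. = FALSE)
  }
  if (length(only_tab) > 0) {
    warning(sprintf("%d table ID(s) absent from FASTA (e.g. %s)",
                    length(only_tab), only_tab[1]), call. = FALSE)
  }
  invisible(intersect(ids, rownames(table)))
}
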