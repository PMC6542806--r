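#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library code never perturbs a caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# provenance-style logging: every filtering step reports before/after counts;
# silenced with options(domitax.verbose = FALSE)
dtx_log <- function(...) {
  if (isTRUE(getOption("domitax.verbose", TRUE))) {
    message("[domitax] ", sprintf(...))
  }
  invisible(NULL)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

#' Match detected module labels to reference labels by majority vote
#'
#' For each detected module, returns the most common reference label among its
#' members (ties broken by first label in sorted order). Useful for aligning
#' network modules with planted niche groups.
#'
#' @param modules named character/factor vector: detected module per node.
#' @param reference named vector of reference labels; names must cover the
#'   names of `modules`.
#' @return named character vector, one reference label per module label.
#' @export
match_modules <- function(modules, reference) {
  if (is.null(names(modules)) || is.null(names(reference))) {
    stop2("both 'modules' and 'reference' must be named")
  }
  missing_ref <- setdiff(names(modules), names(reference))
  if (length(missing_ref) > 0) {
    stop2("no reference label for node(s): %s",
          paste(utils::head(missing_ref, 5), collapse = ", "))
  }
  ref <- as.character(reference[names(modules)])
  vapply(split(ref, as.character(modules)), function(labs) {
    tab <- sort(table(labs), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
}
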