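#' @useDynLib cytosuite, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats median dist hclust cutree as.dist rnorm rgamma rmultinom
#'   pt pwilcox pnorm sd quantile setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

# classed conditions so callers/tests can dispatch on error kind
cs_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "cytosuite_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

cs_warn <- function(msg, class = "cytosuite_warning") {
  warning(structure(
    class = c(class, "cytosuite_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Derive a reproducible child seed from a root seed and a stage name
#'
#' Modules derive their own seeds from the global seed plus a stage label, so
#' inserting or removing one pipeline stage never reshuffles the random draws
#' of the others. Kept strictly below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param stage character stage label (e.g. `"umap"`, `"som"`).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587L)
}

# run expr under a local, restored RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}
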