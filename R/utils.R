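#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t crossprod
#' @importFrom stats rnorm runif rbinom rpois quantile sd cor setNames
#' @importFrom utils read.table write.table head
NULL

# package-level verbosity switch; tests set options(drhgnn.verbose = FALSE)
drh_msg <- function(...) {
  if (isTRUE(getOption("drhgnn.verbose", TRUE))) message(sprintf(...))
  invisible(NULL)
}

drh_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# All randomness funnels through a master seed expanded per stage with fixed
# offsets, kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}

# Local RNG scope: run `expr` under `seed` without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
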