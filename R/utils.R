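#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq pnorm pt phyper mad rnorm runif rbinom rbeta
#'   ppoints sd var setNames wilcox.test
#' @importFrom graphics plot abline
#' @importFrom utils write.table read.delim head
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream-specific child seed from a base seed, staying inside
# 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1009 + stream) %% 2147483647
}

#' Write a data frame as a tab-separated file with header
#'
#' All pipeline outputs are headered TSVs; this wraps the common options.
#'
#' @param x data frame.
#' @param path output file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated file with header
#'
#' @param path input file path.
#' @return data frame with character columns left as-is.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
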