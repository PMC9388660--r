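#' @keywords internal
"_PACKAGE"

#' @importFrom stats rlnorm
#' @importFrom utils head read.delim write.table
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic entry points funnel through this so that results
# are reproducible from an explicit integer seed and no global state leaks.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize gene symbols
#'
#' Trims whitespace and upper-cases symbols. All symbol matching in the
#' package is performed on normalized symbols so that, e.g., mouse-style
#' `Esrrg` and human-style `ESRRG` compare equal unless an explicit symbol
#' map says otherwise.
#'
#' @param x character vector of gene symbols.
#' @return character vector of trimmed, upper-cased symbols.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# Write a data.frame as plain TSV (no quoting, no row names); the on-disk
# interchange format for every intermediate table.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stop_fatal <- function(...) stop(..., call. = FALSE)
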