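#' Read a gene list file
#'
#' One symbol per line; blank lines and `#` comments ignored; symbols
#' normalized (trimmed, upper-cased) and de-duplicated.
#'
#' @param path path to a plain-text gene list.
#' @return character vector of unique normalized symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_fatal("gene list not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(normalize_symbols(x))
}

#' Read a two-column symbol map
#'
#' Tab-delimited, source symbol in the first column, target symbol in the
#' second; used e.g. to map mouse symbols onto human homologs before
#' list comparison.
#'
#' @param path path to a two-column TSV (no header required; a header row
#'   simply maps itself and is harmless).
#' @return data.frame with columns `from`, `to` (normalized symbols).
#' @export
read_symbol_map <- function(path) {
  if (!file.exists(path)) stop_fatal("symbol map not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_fatal("symbol map needs two columns")
  data.frame(from = normalize_symbols(df[[1L]]),
             to = normalize_symbols(df[[2L]]),
             stringsAsFactors = FALSE)
}

#' Apply a symbol map to a gene vector
#'
#' Mapped symbols are replaced; unmapped symbols pass through unchanged.
#'
#' @param genes character vector of symbols.
#' @param map data.frame with columns `from`, `to`, or NULL for identity.
#' @return mapped, de-duplicated symbol vector.
#' @export
apply_symbol_map <- function(genes, map = NULL) {
  genes <- normalize_symbols(genes)
  if (is.null(map)) return(unique(genes))
  i <- match(genes, map$from)
  genes[!is.na(i)] <- map$to[i[!is.na(i)]]
  unique(genes)
}

#' Venn-style overlap report for gene lists
#'
#' Deterministic set arithmetic over two or more gene lists (the counting
#' behind Venn-diagram figures): after optional symbol mapping, every
#' exclusive region of the Venn decomposition is reported with its member
#' symbols (alphabetical) and count. Region counts sum to the size of the
#' union; the common intersection is reported separately.
#'
#' @param lists named list of character vectors (at least two); symbols
#'   are normalized, lists may be empty.
#' @param mapping optional symbol map (data.frame `from`/`to`) applied to
#'   every list before comparison.
#' @return object of class `overlap_report`: list with `membership`
#'   (logical gene-by-list matrix over the union, alphabetical),
#'   `regions` (data.frame `region`, `n`, `genes` — exclusive regions),
#'   `intersection` (symbols common to all lists), `labels`.
#' @export
gene_list_overlap <- function(lists, mapping = NULL) {
  if (length(lists) < 2L)
    stop_fatal("overlap needs at least two gene lists")
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    names(lists) <- paste0("list", seq_along(lists))
  lists <- lapply(lists, apply_symbol_map, map = mapping)

  universe <- sort(unique(unlist(lists, use.names = FALSE)))
  membership <- vapply(lists, function(l) universe %in% l,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(lists)))

  key <- apply(membership, 1L, function(m)
    paste(names(lists)[m], collapse = "&"))
  regions <- lapply(split(universe, key), sort)
  regions <- data.frame(
    region = names(regions),
    n = vapply(regions, length, integer(1L)),
    genes = vapply(regions, paste, character(1L), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL
  )
  regions <- regions[order(regions$region), , drop = FALSE]
  rownames(regions) <- NULL

  structure(list(
    membership = membership,
    regions = regions,
    intersection = universe[rowSums(membership) == ncol(membership)],
    labels = names(lists)),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report over", length(x$labels), "lists; union",
      nrow(x$membership), "genes; common intersection",
      length(x$intersection), "\n")
  print(x$regions[, c("region", "n")], row.names = FALSE)
  invisible(x)
}

#' Write an overlap report to TSV
#'
#' @param report an `overlap_report`.
#' @param path output path for the region table.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(report, path) write_tsv(report$regions, path)
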