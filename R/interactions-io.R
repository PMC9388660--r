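#' Default BioGRID TAB3 column dialect
#'
#' Maps the seven semantic fields the pipeline needs onto the column names
#' used by BioGRID TAB3 dumps. Pass a modified copy to
#' [read_interaction_table()] to read other tabular interaction dumps.
#'
#' @param ... named overrides, e.g. `publication_id = "PMID"`.
#' @return named character vector mapping semantic field names to column
#'   names in the file.
#' @export
#' @examples
#' biogrid_tab3_dialect()
#' biogrid_tab3_dialect(publication_id = "Pubmed ID")
biogrid_tab3_dialect <- function(...) {
  dialect <- c(
    interactor_a             = "Official Symbol Interactor A",
    interactor_b             = "Official Symbol Interactor B",
    organism_a               = "Organism ID Interactor A",
    organism_b               = "Organism ID Interactor B",
    publication_id           = "Publication Source",
    experimental_system      = "Experimental System",
    experimental_system_type = "Experimental System Type"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(dialect))
    if (length(bad))
      stop_fatal("unknown dialect field(s): ", paste(bad, collapse = ", "))
    dialect[names(overrides)] <- overrides
  }
  dialect
}

#' Read an interaction evidence table
#'
#' Parses a tab-delimited interaction evidence file (BioGRID TAB3 layout by
#' default) into one evidence record per data row. Gene symbols are trimmed
#' and upper-cased; comment lines are skipped. The TAB3 header line itself
#' starts with `#`, so the first non-empty line is always taken as the
#' header (with any leading `#` stripped) and later `#`-prefixed lines are
#' treated as comments.
#'
#' Rows with an empty interactor symbol or a non-numeric/non-positive taxon
#' id are skipped, counted, and reported via a message; a missing mapped
#' column is a fatal configuration error.
#'
#' @param path path to a tab-delimited evidence file.
#' @param dialect named character vector from [biogrid_tab3_dialect()]
#'   mapping semantic fields to column names in the file.
#' @return data.frame of evidence records with columns `interactor_a`,
#'   `interactor_b`, `organism_a`, `organism_b`, `publication_id`,
#'   `experimental_system`, `experimental_system_type`; the number of
#'   skipped rows is attached as attribute `n_skipped`.
#' @seealso [collapse_to_edges()], [filter_edges()]
#' @export
read_interaction_table <- function(path, dialect = biogrid_tab3_dialect()) {
  if (!file.exists(path)) stop_fatal("evidence file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_fatal("evidence file is empty: ", path)

  header <- sub("^#", "", lines[[1L]])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[!startsWith(body, "#")]

  needed <- c("interactor_a", "interactor_b", "organism_a", "organism_b",
              "publication_id", "experimental_system",
              "experimental_system_type")
  missing_fields <- setdiff(needed, names(dialect))
  if (length(missing_fields))
    stop_fatal("dialect is missing field(s): ",
               paste(missing_fields, collapse = ", "))
  idx <- match(dialect[needed], cols)
  if (anyNA(idx)) {
    absent <- dialect[needed][is.na(idx)]
    stop_fatal("mapped column(s) not found in file: ",
               paste(absent, collapse = ", "))
  }

  if (!length(body)) {
    out <- data.frame(interactor_a = character(), interactor_b = character(),
                      organism_a = integer(), organism_b = integer(),
                      publication_id = character(),
                      experimental_system = character(),
                      experimental_system_type = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }

  fields <- strsplit(body, "\t", fixed = TRUE)
  pick <- function(j) vapply(fields, function(f) {
    if (j <= length(f)) f[[j]] else NA_character_
  }, character(1L))

  rec <- data.frame(
    interactor_a = normalize_symbols(pick(idx[1L])),
    interactor_b = normalize_symbols(pick(idx[2L])),
    organism_a = suppressWarnings(as.integer(pick(idx[3L]))),
    organism_b = suppressWarnings(as.integer(pick(idx[4L]))),
    publication_id = trimws(pick(idx[5L])),
    experimental_system = trimws(pick(idx[6L])),
    experimental_system_type = tolower(trimws(pick(idx[7L]))),
    stringsAsFactors = FALSE
  )
  rec$experimental_system_type[
    !rec$experimental_system_type %in% c("physical", "genetic")] <- "unknown"

  ok <- nzchar(rec$interactor_a) & nzchar(rec$interactor_b) &
    !is.na(rec$organism_a) & rec$organism_a > 0L &
    !is.na(rec$organism_b) & rec$organism_b > 0L
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    message("read_interaction_table: skipped ", n_skipped,
            " malformed row(s)")
  out <- rec[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Collapse evidence records into undirected edges
#'
#' Keeps records where both interactors belong to the target taxon, drops
#' self-interactions, de-duplicates identical
#' (pair, publication, experimental system) evidence tuples, and emits one
#' edge per unordered gene pair with distinct-evidence counts. The pair is
#' stored in canonical lexicographic order.
#'
#' @param records evidence data.frame from [read_interaction_table()].
#' @param taxon NCBI taxon id both interactors must carry (default 9606,
#'   human).
#' @param system_type `"any"` (default) to count physical and genetic
#'   evidence alike, or `"physical"`/`"genetic"` to restrict.
#' @return data.frame with columns `gene_a`, `gene_b`, `n_publications`,
#'   `n_methods`, `n_evidence`, one row per unordered pair.
#' @export
collapse_to_edges <- function(records, taxon = 9606L,
                              system_type = c("any", "physical", "genetic")) {
  system_type <- match.arg(system_type)
  stopifnot(is.numeric(taxon), length(taxon) == 1L, taxon > 0)

  keep <- records$organism_a == taxon & records$organism_b == taxon &
    records$interactor_a != records$interactor_b
  if (system_type != "any")
    keep <- keep & records$experimental_system_type == system_type
  r <- records[keep, , drop = FALSE]

  empty <- data.frame(gene_a = character(), gene_b = character(),
                      n_publications = integer(), n_methods = integer(),
                      n_evidence = integer(), stringsAsFactors = FALSE)
  if (!nrow(r)) {
    warning("collapse_to_edges: no records survive the taxon/self-loop filter")
    return(empty)
  }

  a <- pmin(r$interactor_a, r$interactor_b)
  b <- pmax(r$interactor_a, r$interactor_b)
  pair <- paste(a, b, sep = "\r")

  # one row per distinct (pair, publication, system) evidence tuple
  tup <- !duplicated(paste(pair, r$publication_id, r$experimental_system,
                           sep = "\r"))
  pair <- pair[tup]
  pub <- r$publication_id[tup]
  sys <- r$experimental_system[tup]

  n_distinct_by <- function(val, grp) {
    first <- !duplicated(paste(grp, val, sep = "\r"))
    tab <- table(grp[first])
    as.integer(tab)[match(levels(factor(grp)), names(tab))]
  }
  grp <- factor(pair)
  lev <- levels(grp)
  ab <- do.call(rbind, strsplit(lev, "\r", fixed = TRUE))
  out <- data.frame(
    gene_a = ab[, 1L],
    gene_b = ab[, 2L],
    n_publications = n_distinct_by(pub, pair),
    n_methods = n_distinct_by(sys, pair),
    n_evidence = as.integer(table(grp)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Filter edges by evidence support
#'
#' Retains an edge when it is supported by at least `min_publications`
#' distinct publications *or* at least `min_methods` distinct experimental
#' systems — a disjunctive rule, so multi-method single-publication evidence
#' also qualifies. Input order is preserved and the operation is idempotent.
#'
#' @param edges edge data.frame from [collapse_to_edges()].
#' @param min_publications minimum distinct publications (default 2).
#' @param min_methods minimum distinct experimental systems (default 2).
#' @return the retained subset of `edges`.
#' @export
filter_edges <- function(edges, min_publications = 2L, min_methods = 2L) {
  stopifnot(min_publications >= 1L, min_methods >= 1L)
  keep <- edges$n_publications >= min_publications |
    edges$n_methods >= min_methods
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an edge table to TSV
#'
#' @param edges edge data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) write_tsv(edges, path)
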