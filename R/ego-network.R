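#' Build the PPI graph from an edge table
#'
#' Instantiates an undirected simple graph over gene symbols: one node per
#' distinct endpoint, at most one edge per unordered pair, no self-loops.
#'
#' @param edges edge data.frame with gene symbols in the first two columns
#'   (as produced by [collapse_to_edges()] / [filter_edges()]).
#' @return an undirected simple [igraph::igraph] object.
#' @export
build_ppi_graph <- function(edges) {
  if (!nrow(edges)) return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(edges[, 1:2, drop = FALSE],
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Restrict a graph to an allowed gene set
#'
#' Induced subgraph on the intersection of the graph's nodes with
#' `allowed`: only edges whose both endpoints survive are kept. This is
#' the cell-type restriction step — `allowed` is typically
#' [genes_present()] for the target clusters.
#'
#' @param graph an igraph PPI graph.
#' @param allowed character vector of allowed gene symbols.
#' @return the induced subgraph.
#' @export
restrict_to_genes <- function(graph, allowed) {
  keep <- intersect(igraph::V(graph)$name, normalize_symbols(allowed))
  igraph::induced_subgraph(graph, keep)
}

#' Resolve a seed gene list against a graph
#'
#' Splits the input seed genes into those present in the graph (which
#' induce ego communities) and those missing (which induce none, but are
#' restored to the final convergence list).
#'
#' @param genes character vector of seed gene symbols.
#' @param graph an igraph PPI graph.
#' @return object of class `seed_list` with elements `genes`, `present`,
#'   `missing`.
#' @export
seed_list <- function(genes, graph) {
  genes <- unique(normalize_symbols(genes))
  genes <- genes[nzchar(genes)]
  present <- genes[genes %in% igraph::V(graph)$name]
  structure(list(genes = genes, present = present,
                 missing = setdiff(genes, present)),
            class = "seed_list")
}

#' @export
print.seed_list <- function(x, ...) {
  cat("seed_list:", length(x$genes), "genes (", length(x$present),
      "in graph,", length(x$missing), "missing )\n")
  invisible(x)
}

as_seed_list <- function(seeds, graph) {
  if (inherits(seeds, "seed_list")) seeds else seed_list(seeds, graph)
}

#' Ego community of a gene
#'
#' The community of a gene is the set of nodes at unweighted shortest-path
#' distance at most `radius` from it, including the gene itself
#' (distance 0). The default radius of 2 edges is the definition used
#' throughout the convergence analysis.
#'
#' @param graph an igraph PPI graph.
#' @param gene a gene symbol present in the graph.
#' @param radius maximum hop distance (default 2).
#' @return character vector of community member symbols.
#' @export
ego_community <- function(graph, gene, radius = 2L) {
  gene <- normalize_symbols(gene)
  stopifnot(length(gene) == 1L, radius >= 0L)
  if (!gene %in% igraph::V(graph)$name)
    stop_fatal("gene not in graph: ", gene)
  igraph::ego(graph, order = radius, nodes = gene)[[1L]]$name
}

# Ego balls (as integer vertex indices) for every node, radius hops.
# The workhorse for both observed membership and the Monte Carlo null;
# by undirected symmetry, gene g belongs to seed s's community iff s lies
# in g's ball.
node_balls <- function(graph, radius = 2L) {
  lapply(igraph::ego(graph, order = radius,
                     nodes = igraph::V(graph), mindist = 0L),
         as.integer)
}

#' Community membership statistics for a seed list
#'
#' Forms one ego community per seed gene present in the graph and counts,
#' for every gene, how many of those communities contain it (the
#' membership number). The membership proportion is the membership number
#' divided by the number of communities. Genes contained in no community
#' are omitted (sparse representation); every present seed has membership
#' number at least 1, since it lies in its own community.
#'
#' @param graph an igraph PPI graph.
#' @param seeds a [seed_list()] or character vector of seed symbols.
#' @param radius community radius in edges (default 2).
#' @return object of class `community_stats`: a list with `table` (a
#'   data.frame of `gene`, `membership_number`, `membership_proportion`,
#'   `is_seed`), `seeds`, `n_communities`, `radius`.
#' @export
membership_stats <- function(graph, seeds, radius = 2L) {
  seeds <- as_seed_list(seeds, graph)
  if (!length(seeds$present))
    stop_fatal("empty seed intersection: no seed gene is in the graph")
  if (length(seeds$missing))
    message("membership_stats: ", length(seeds$missing),
            " seed gene(s) absent from the graph")
  nodes <- igraph::V(graph)$name
  balls <- igraph::ego(graph, order = radius, nodes = seeds$present)
  counts <- tabulate(unlist(lapply(balls, as.integer), use.names = FALSE),
                     nbins = length(nodes))
  nz <- which(counts > 0L)
  n_comm <- length(seeds$present)
  tab <- data.frame(
    gene = nodes[nz],
    membership_number = counts[nz],
    membership_proportion = counts[nz] / n_comm,
    is_seed = nodes[nz] %in% seeds$genes,
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab <- tab[order(tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, seeds = seeds, n_communities = n_comm,
                 radius = as.integer(radius)),
            class = "community_stats")
}

#' @export
print.community_stats <- function(x, ...) {
  cat("community_stats:", x$n_communities, "communities (radius",
      x$radius, "),", nrow(x$table), "member genes\n")
  invisible(x)
}

#' Write a membership table to TSV
#'
#' @param stats a `community_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_membership_table <- function(stats, path) write_tsv(stats$table, path)
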