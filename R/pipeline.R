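#' Validated pipeline configuration
#'
#' Collects paths and parameters for a full convergence run and validates
#' them before any computation. Defaults mirror the analysis parameters
#' used throughout the package: evidence from at least 2 publications or
#' 2 experimental methods, human taxon 9606, community radius 2 edges,
#' 1000 Monte Carlo replicates, a 3-SD overrepresentation filter, a
#' minimum membership number of 2, and a top-25 target list.
#'
#' @param interactions path to the interaction evidence table.
#' @param atlas path to the gene-by-cluster expression atlas.
#' @param seeds path to the seed gene list (one symbol per line).
#' @param output_dir directory for all run artifacts (created if needed).
#' @param target_clusters cluster labels defining the target cell type.
#' @param symbol_map optional path to a two-column symbol map applied to
#'   the seed list before analysis.
#' @param dialect column dialect for the evidence table.
#' @param taxon NCBI taxon id for the organism filter.
#' @param min_publications,min_methods evidence-filter thresholds.
#' @param min_level atlas presence threshold.
#' @param radius community radius in edges.
#' @param replicates Monte Carlo replicates.
#' @param sd_multiplier SD-filter multiplier.
#' @param min_membership minimum membership number.
#' @param top_n size of the final target list.
#' @param include_restored_seeds score restored seeds too.
#' @param rng_seed integer seed controlling all randomness of the run.
#' @return object of class `run_config`.
#' @export
run_config <- function(interactions, atlas, seeds, output_dir,
                       target_clusters,
                       symbol_map = NULL,
                       dialect = biogrid_tab3_dialect(),
                       taxon = 9606L,
                       min_publications = 2L, min_methods = 2L,
                       min_level = 0, radius = 2L, replicates = 1000L,
                       sd_multiplier = 3, min_membership = 2L,
                       top_n = 25L, include_restored_seeds = FALSE,
                       rng_seed = 1L) {
  for (p in c(interactions = interactions, atlas = atlas, seeds = seeds,
              if (!is.null(symbol_map)) c(symbol_map = symbol_map)))
    if (!file.exists(p)) stop_fatal("input path does not exist: ", p)
  num_ok <- function(x, lo) is.numeric(x) && length(x) == 1L &&
    is.finite(x) && x >= lo
  if (!num_ok(min_publications, 1) || !num_ok(min_methods, 1))
    stop_fatal("evidence thresholds must be >= 1")
  if (!num_ok(radius, 0)) stop_fatal("radius must be >= 0")
  if (!num_ok(replicates, 1)) stop_fatal("replicates must be >= 1")
  if (!num_ok(sd_multiplier, 0)) stop_fatal("sd_multiplier must be >= 0")
  if (!num_ok(min_membership, 1)) stop_fatal("min_membership must be >= 1")
  if (!num_ok(top_n, 1)) stop_fatal("top_n must be >= 1")
  if (!num_ok(taxon, 1)) stop_fatal("taxon must be a positive integer")
  if (!is.character(target_clusters) || !length(target_clusters))
    stop_fatal("target_clusters must name at least one cluster")
  structure(list(
    interactions = interactions, atlas = atlas, seeds = seeds,
    output_dir = output_dir, target_clusters = target_clusters,
    symbol_map = symbol_map, dialect = dialect, taxon = taxon,
    min_publications = min_publications, min_methods = min_methods,
    min_level = min_level, radius = radius, replicates = replicates,
    sd_multiplier = sd_multiplier, min_membership = min_membership,
    top_n = top_n, include_restored_seeds = include_restored_seeds,
    rng_seed = rng_seed), class = "run_config")
}

#' Run the full convergence pipeline
#'
#' Executes every stage in order — read evidence, collapse and filter
#' edges, restrict to genes present in the target cell type, build the
#' graph, compute seed community membership, simulate the Monte Carlo
#' null, build the convergence table, score and rank targets — writing
#' every intermediate table, a stage-count log and a machine-readable
#' JSON manifest (the config plus the counts) into `config$output_dir`.
#' Reruns with an identical config are bit-identical.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `edges`, `graph`, `stats`, `null`,
#'   `convergence`, `scores`, `top`, `counts`, `manifest` (path).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage '", name, "': ",
                        conditionMessage(e)), out("FAILED"))
      stop_fatal("pipeline stage '", name, "' failed: ",
                 conditionMessage(e))
    })
  }

  records <- stage("read_evidence",
                   read_interaction_table(config$interactions,
                                          config$dialect))
  counts$evidence_rows <- nrow(records)
  counts$evidence_skipped <- attr(records, "n_skipped")

  edges <- stage("collapse", collapse_to_edges(records, config$taxon))
  counts$collapsed_edges <- nrow(edges)
  edges <- stage("evidence_filter",
                 filter_edges(edges, config$min_publications,
                              config$min_methods))
  counts$filtered_edges <- nrow(edges)
  write_edge_table(edges, out("edges.tsv"))

  atlas <- stage("read_atlas", read_atlas(config$atlas))
  present <- stage("cell_type_presence",
                   genes_present(atlas, config$target_clusters,
                                 config$min_level))
  counts$genes_present_in_cell_type <- length(present)

  graph <- stage("build_graph", build_ppi_graph(edges))
  graph <- stage("cell_type_restrict", restrict_to_genes(graph, present))
  counts$graph_nodes <- igraph::vcount(graph)
  counts$graph_edges <- igraph::ecount(graph)

  seed_genes <- stage("read_seeds", read_gene_list(config$seeds))
  if (!is.null(config$symbol_map))
    seed_genes <- apply_symbol_map(seed_genes,
                                   read_symbol_map(config$symbol_map))
  seeds <- seed_list(seed_genes, graph)
  counts$seeds_total <- length(seeds$genes)
  counts$seeds_present <- length(seeds$present)
  counts$seeds_missing <- length(seeds$missing)
  write_gene_list(seeds$missing, out("seeds_missing.txt"))

  stats <- stage("membership", membership_stats(graph, seeds, config$radius))
  write_membership_table(stats, out("membership.tsv"))

  null <- stage("monte_carlo_null",
                simulate_null(graph, length(seeds$present),
                              replicates = config$replicates,
                              radius = config$radius,
                              rng_seed = config$rng_seed))
  write_tsv(null$table, out("null_summary.tsv"))

  conv <- stage("convergence",
                convergence_table(stats, null,
                                  sd_multiplier = config$sd_multiplier,
                                  min_membership = config$min_membership))
  counts$genes_retained <- sum(conv$retained)
  counts$genes_restored <- sum(conv$is_restored_seed)
  write_convergence_table(conv, out("convergence.tsv"))

  metrics <- stage("atlas_metrics",
                   atlas_metrics(atlas, conv$gene, config$target_clusters,
                                 config$min_level))
  write_tsv(metrics, out("atlas_metrics.tsv"))

  scores <- stage("composite_scores",
                  composite_scores(conv, metrics,
                                   config$include_restored_seeds))
  counts$genes_scored <- nrow(scores)
  write_score_table(scores, out("scores.tsv"))
  top <- top_targets(scores, config$top_n)
  write_gene_list(top, out("top_targets.txt"))

  manifest <- c(config[setdiff(names(config), "dialect")],
                list(dialect = as.list(config$dialect), counts = counts))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  log_lines <- paste0(names(counts), ": ",
                      vapply(counts, as.character, character(1L)))
  writeLines(log_lines, out("run_log.txt"))

  invisible(list(edges = edges, graph = graph, stats = stats, null = null,
                 convergence = conv, scores = scores, top = top,
                 counts = counts, manifest = out("manifest.json")))
}
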