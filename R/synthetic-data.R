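# Synthetic fixtures with known ground truth. The generators emit the same
# file formats the pipeline consumes, so every stage can be exercised
# end-to-end without any external download.

synthetic_gene_symbols <- function(n, prefix = "G") {
  sprintf("%s%04d", prefix, seq_len(n))
}

#' Generate a synthetic interaction evidence table
#'
#' Samples `n_pairs` distinct gene pairs and emits a BioGRID-TAB3-layout
#' evidence table with controllable evidence multiplicity: each pair gets
#' one base evidence row, an extra row from a second publication with
#' probability `p_second_pub`, and an extra row from a second experimental
#' system with probability `p_second_method`. Independently, each emitted
#' row is reassigned to an off-target organism with probability
#' `p_off_taxon`. The returned ground truth records, per pair, the
#' distinct on-taxon publication and method counts, so the downstream
#' collapse/filter results can be checked exactly.
#'
#' @param n_genes number of genes in the symbol pool.
#' @param n_pairs number of distinct interacting pairs to sample.
#' @param p_second_pub probability of a second-publication evidence row.
#' @param p_second_method probability of a second-method evidence row.
#' @param p_off_taxon per-row probability of an off-target organism.
#' @param taxon target taxon id written on on-target rows (default 9606).
#' @param off_taxon organism id used for off-target rows (default 10090).
#' @param rng_seed integer seed; generation is deterministic given it.
#' @param path optional output path; when given, the table is written
#'   there as a TAB3-style TSV.
#' @return list with `records` (the file-layout data.frame), `truth`
#'   (per-pair data.frame: `gene_a`, `gene_b`, `n_publications`,
#'   `n_methods`, `n_evidence` counting distinct on-taxon evidence, and
#'   `retained_default` — whether [filter_edges()] at defaults keeps the
#'   pair), and `path`.
#' @export
generate_interaction_table <- function(n_genes, n_pairs,
                                       p_second_pub = 0.5,
                                       p_second_method = 0.3,
                                       p_off_taxon = 0,
                                       taxon = 9606L, off_taxon = 10090L,
                                       rng_seed = 1L, path = NULL) {
  max_pairs <- n_genes * (n_genes - 1) / 2
  if (n_pairs > max_pairs)
    stop_fatal("n_pairs (", n_pairs, ") exceeds the ", max_pairs,
               " distinct pairs available among ", n_genes, " genes")
  genes <- synthetic_gene_symbols(n_genes)

  with_seed(rng_seed, {
    pair_idx <- sample.int(max_pairs, n_pairs)
    # unrank the i-th pair (row-major upper triangle) without enumeration
    j <- ceiling((1 + sqrt(1 + 8 * pair_idx)) / 2)
    i <- pair_idx - (j - 1) * (j - 2) / 2
    ga <- genes[i]; gb <- genes[j]

    base_sys <- "Two-hybrid"; alt_sys <- "Affinity Capture-MS"
    extra_pub <- runif(n_pairs) < p_second_pub
    extra_met <- runif(n_pairs) < p_second_method
    rec <- rbind(
      data.frame(pair = seq_len(n_pairs), a = ga, b = gb,
                 pub = sprintf("PUBMED:%d", 100000L + seq_len(n_pairs)),
                 sys = base_sys, stringsAsFactors = FALSE),
      if (any(extra_pub)) data.frame(
        pair = which(extra_pub), a = ga[extra_pub], b = gb[extra_pub],
        pub = sprintf("PUBMED:%d", 200000L + which(extra_pub)),
        sys = base_sys, stringsAsFactors = FALSE),
      if (any(extra_met)) data.frame(
        pair = which(extra_met), a = ga[extra_met], b = gb[extra_met],
        pub = sprintf("PUBMED:%d", 100000L + which(extra_met)),
        sys = alt_sys, stringsAsFactors = FALSE)
    )
    rec$organism <- ifelse(runif(nrow(rec)) < p_off_taxon,
                           as.integer(off_taxon), as.integer(taxon))
  })

  on_tax <- rec$organism == taxon
  per_pair <- function(f) vapply(seq_len(n_pairs), function(p) {
    rows <- on_tax & rec$pair == p
    f(rows)
  }, integer(1L))
  truth <- data.frame(
    gene_a = ga, gene_b = gb,
    n_publications = per_pair(function(r) length(unique(rec$pub[r]))),
    n_methods = per_pair(function(r) length(unique(rec$sys[r]))),
    n_evidence = per_pair(function(r)
      length(unique(paste(rec$pub[r], rec$sys[r])))),
    stringsAsFactors = FALSE
  )
  truth$retained_default <- truth$n_publications >= 2L | truth$n_methods >= 2L
  truth <- truth[order(truth$gene_a, truth$gene_b), , drop = FALSE]
  rownames(truth) <- NULL

  records <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    "Official Symbol Interactor A" = rec$a,
    "Official Symbol Interactor B" = rec$b,
    "Experimental System" = rec$sys,
    "Experimental System Type" = "physical",
    "Publication Source" = rec$pub,
    "Organism ID Interactor A" = rec$organism,
    "Organism ID Interactor B" = rec$organism
  )
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(paste0("#", paste(colnames(records), collapse = "\t")), con)
    utils::write.table(records, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  list(records = records, truth = truth, path = path)
}

#' Generate a synthetic expression atlas with planted enrichment
#'
#' Draws a log-normal baseline for every (gene, cluster) cell and
#' multiplies the designated enriched genes' values in the target
#' clusters by `enrichment_factor`, so their expected relative enrichment
#' equals the factor. `sdlog = 0` gives the deterministic noise-free
#' limit with exact factor recovery.
#'
#' @param n_genes,n_clusters atlas dimensions.
#' @param enriched_genes symbols (from the `G0001...` pool) whose target
#'   expression is boosted; may be empty.
#' @param enrichment_factor multiplicative boost (> 1).
#' @param n_target_clusters how many leading clusters form the target
#'   cell type (default 1); cluster labels are `SN_1, SN_2, ...` for
#'   targets and `C1, C2, ...` for the rest.
#' @param sdlog log-scale noise SD of the baseline (default 0.5).
#' @param rng_seed integer seed.
#' @return an [expression_atlas()]; the target cluster labels and the
#'   enriched set are attached as attributes `target_clusters` and
#'   `enriched_genes`.
#' @export
generate_atlas <- function(n_genes, n_clusters, enriched_genes = character(),
                           enrichment_factor = 10, n_target_clusters = 1L,
                           sdlog = 0.5, rng_seed = 1L) {
  stopifnot(enrichment_factor > 1, n_target_clusters >= 1L,
            n_target_clusters < n_clusters)
  genes <- synthetic_gene_symbols(n_genes)
  clusters <- c(paste0("SN_", seq_len(n_target_clusters)),
                paste0("C", seq_len(n_clusters - n_target_clusters)))
  vals <- with_seed(rng_seed,
    matrix(rlnorm(n_genes * n_clusters, meanlog = 1, sdlog = sdlog),
           nrow = n_genes, dimnames = list(genes, clusters)))
  enriched_genes <- normalize_symbols(enriched_genes)
  hit <- intersect(enriched_genes, genes)
  targets <- clusters[seq_len(n_target_clusters)]
  vals[hit, targets] <- vals[hit, targets] * enrichment_factor
  atlas <- expression_atlas(vals)
  attr(atlas, "target_clusters") <- targets
  attr(atlas, "enriched_genes") <- hit
  atlas
}

#' Generate a graph with planted convergent hubs
#'
#' Builds a random background graph (Erdős–Rényi with edge probability
#' `p_background`, or a degree-preserving configuration-model rewiring of
#' it) over `n_nodes` genes, designates `n_seeds` seed genes and
#' `n_hubs` hub genes (disjoint), and wires every hub to every seed. A
#' hub is therefore within one edge of every seed, forcing membership
#' proportion 1 at radius 2 — the known ground truth for recovery tests.
#'
#' @param n_nodes,n_seeds,n_hubs counts with `n_seeds + n_hubs <= n_nodes`.
#' @param p_background background edge probability.
#' @param model `"erdos-renyi"` (default) or `"configuration"` (background
#'   degree sequence preserved under rewiring, for stress tests).
#' @param rng_seed integer seed.
#' @return list with `graph` (igraph over all `n_nodes` genes, isolated
#'   nodes included), `seeds` (a [seed_list()]), `planted_hubs`,
#'   `background_nodes`.
#' @export
generate_planted_convergence <- function(n_nodes, n_seeds, n_hubs,
                                         p_background,
                                         model = c("erdos-renyi",
                                                   "configuration"),
                                         rng_seed = 1L) {
  model <- match.arg(model)
  if (n_seeds + n_hubs > n_nodes)
    stop_fatal("n_seeds + n_hubs exceeds n_nodes")
  stopifnot(n_seeds >= 1L)
  genes <- synthetic_gene_symbols(n_nodes)
  g <- with_seed(rng_seed, {
    bg <- igraph::sample_gnp(n_nodes, p_background, directed = FALSE)
    if (model == "configuration" && igraph::ecount(bg) > 1L)
      bg <- igraph::sample_degseq(igraph::degree(bg), method = "vl")
    igraph::V(bg)$name <- genes
    seed_ids <- seq_len(n_seeds)
    hub_ids <- n_seeds + seq_len(n_hubs)
    if (n_hubs >= 1L) {
      planted <- rbind(rep(hub_ids, each = n_seeds),
                       rep(seed_ids, times = n_hubs))
      bg <- igraph::add_edges(bg, as.vector(planted))
    }
    igraph::simplify(bg)
  })
  seeds <- seed_list(genes[seq_len(n_seeds)], g)
  hubs <- if (n_hubs >= 1L) genes[n_seeds + seq_len(n_hubs)] else character()
  list(graph = g, seeds = seeds, planted_hubs = hubs,
       background_nodes = setdiff(genes, c(seeds$genes, hubs)))
}

#' Write a seed gene list file
#'
#' @param genes character vector of symbols.
#' @param path output path (one symbol per line).
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(normalize_symbols(genes), path)
  invisible(path)
}
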