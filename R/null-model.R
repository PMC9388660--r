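#' Monte Carlo null for membership proportions
#'
#' Draws `replicates` random seed sets of size `seed_set_size`, uniformly
#' without replacement from the graph's node set, and records every node's
#' membership proportion in each replicate. Returns the per-node mean and
#' sample standard deviation (divisor R - 1) across replicates; nodes
#' falling in no community of a replicate contribute proportion 0 there.
#'
#' Implementation note: by undirected symmetry a node's membership number
#' under a seed set S equals the number of seeds inside the node's own
#' ego ball, so each replicate reduces to one tabulation over the sampled
#' seeds' precomputed balls.
#'
#' @param graph an igraph PPI graph.
#' @param seed_set_size number of seeds per random set (use
#'   `length(seeds$present)` to match an observed analysis).
#' @param replicates number of random sets (default 1000).
#' @param radius community radius in edges (default 2).
#' @param rng_seed integer seed; identical seeds give bit-identical
#'   summaries.
#' @return object of class `null_summary`: data.frame `table` with
#'   columns `gene`, `mean`, `sd` (one row per graph node), plus fields
#'   `replicates`, `seed_set_size`, `radius`, `rng_seed`, `method`.
#' @seealso [closed_form_null()] for the exact hypergeometric counterpart.
#' @export
simulate_null <- function(graph, seed_set_size, replicates = 1000L,
                          radius = 2L, rng_seed = 1L) {
  n <- igraph::vcount(graph)
  k <- as.integer(seed_set_size)
  r <- as.integer(replicates)
  if (k < 1L || k > n)
    stop_fatal("seed_set_size must be between 1 and the node count (", n, ")")
  if (r < 1L) stop_fatal("replicates must be >= 1")

  balls <- node_balls(graph, radius)
  sum_p <- numeric(n)
  sum_p2 <- numeric(n)
  with_seed(rng_seed, {
    for (i in seq_len(r)) {
      s <- sample.int(n, k)
      p <- tabulate(unlist(balls[s], use.names = FALSE), nbins = n) / k
      sum_p <- sum_p + p
      sum_p2 <- sum_p2 + p * p
    }
  })
  m <- sum_p / r
  sd <- if (r > 1L) sqrt(pmax(sum_p2 - r * m * m, 0) / (r - 1L))
        else numeric(n)
  structure(list(
    table = data.frame(gene = igraph::V(graph)$name, mean = m, sd = sd,
                       stringsAsFactors = FALSE, row.names = NULL),
    replicates = r, seed_set_size = k, radius = as.integer(radius),
    rng_seed = rng_seed, method = "monte-carlo"),
    class = "null_summary")
}

#' Exact hypergeometric null for membership proportions
#'
#' Analytic counterpart of [simulate_null()]. For a node whose ego ball
#' (radius `radius`) contains m of the graph's N nodes, the number of
#' random seeds falling inside the ball is hypergeometric(N, m, k), so the
#' membership proportion has mean m/N and variance
#' (1/k) (m/N) (1 - m/N) (N - k)/(N - 1). No randomness is involved.
#'
#' @inheritParams simulate_null
#' @return a `null_summary` with `method = "closed-form"` and
#'   `replicates = Inf`.
#' @export
closed_form_null <- function(graph, seed_set_size, radius = 2L) {
  n <- igraph::vcount(graph)
  k <- as.integer(seed_set_size)
  if (k < 1L || k > n)
    stop_fatal("seed_set_size must be between 1 and the node count (", n, ")")
  m <- vapply(node_balls(graph, radius), length, integer(1L))
  p <- m / n
  v <- if (n > 1L) (1 / k) * p * (1 - p) * ((n - k) / (n - 1)) else rep(0, n)
  structure(list(
    table = data.frame(gene = igraph::V(graph)$name, mean = p, sd = sqrt(v),
                       stringsAsFactors = FALSE, row.names = NULL),
    replicates = Inf, seed_set_size = k, radius = as.integer(radius),
    rng_seed = NA_integer_, method = "closed-form"),
    class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat("null_summary (", x$method, "): ", nrow(x$table), " nodes, k = ",
      x$seed_set_size, ", radius = ", x$radius,
      if (is.finite(x$replicates)) paste0(", R = ", x$replicates), "\n",
      sep = "")
  invisible(x)
}

#' Convergence table: fold enrichment, overrepresentation filters, seed
#' restoration
#'
#' Joins observed membership statistics with the null summary and applies
#' the two exclusion rules of the convergence analysis:
#' \itemize{
#'   \item the standard-deviation filter — a gene passes when its observed
#'     membership proportion is at least `expected_mean +
#'     sd_multiplier * expected_sd` (genes below 3 SD above the null mean
#'     are excluded at defaults);
#'   \item the membership-number filter — a gene passes when it belongs to
#'     at least `min_membership` communities (genes found in a single
#'     community are excluded at defaults, however enriched).
#' }
#' Fold enrichment (the "connectivity value") is the observed proportion
#' divided by the expected mean, floored at `1/(replicates *
#' n_communities)` — the smallest nonzero proportion resolvable at R
#' replicates — to avoid division by zero while preserving ranking.
#'
#' Seed genes that do not pass both filters are restored to the output
#' with `is_restored_seed = TRUE`, carrying their raw statistics (zeros if
#' absent from the graph altogether); the final convergent list is the
#' rows with `retained = TRUE`.
#'
#' @param stats a `community_stats` object from [membership_stats()].
#' @param null a `null_summary` from [simulate_null()] or
#'   [closed_form_null()] computed on the same graph and radius.
#' @param sd_multiplier SD-filter multiplier (default 3).
#' @param min_membership minimum membership number (default 2).
#' @return data.frame of class `convergence_table` with columns `gene`,
#'   `observed_membership_number`, `observed_proportion`, `expected_mean`,
#'   `expected_sd`, `fold_enrichment`, `passes_sd_filter`,
#'   `passes_membership_filter`, `is_restored_seed`, `retained`.
#' @export
convergence_table <- function(stats, null, sd_multiplier = 3,
                              min_membership = 2L) {
  stopifnot(inherits(stats, "community_stats"),
            inherits(null, "null_summary"))
  if (stats$radius != null$radius)
    stop_fatal("stats and null use different radii (", stats$radius,
               " vs ", null$radius, ")")
  obs <- stats$table
  idx <- match(obs$gene, null$table$gene)
  if (anyNA(idx))
    stop_fatal("node universes differ: ", sum(is.na(idx)),
               " observed gene(s) missing from the null summary")

  e_mean <- null$table$mean[idx]
  e_sd <- null$table$sd[idx]
  floor_p <- if (is.finite(null$replicates))
    1 / (null$replicates * stats$n_communities) else 0
  denom <- pmax(e_mean, floor_p)
  fold <- ifelse(denom > 0, obs$membership_proportion / denom,
                 ifelse(obs$membership_proportion > 0, Inf, 0))

  out <- data.frame(
    gene = obs$gene,
    observed_membership_number = obs$membership_number,
    observed_proportion = obs$membership_proportion,
    expected_mean = e_mean,
    expected_sd = e_sd,
    fold_enrichment = fold,
    passes_sd_filter =
      obs$membership_proportion >= e_mean + sd_multiplier * e_sd,
    passes_membership_filter = obs$membership_number >= min_membership,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$is_restored_seed <- FALSE
  passes <- out$passes_sd_filter & out$passes_membership_filter

  # restore input seeds: flag failing seeds in place, append absent ones
  seed_genes <- stats$seeds$genes
  out$is_restored_seed <- out$gene %in% seed_genes & !passes
  absent <- setdiff(seed_genes, out$gene)
  if (length(absent)) {
    out <- rbind(out, data.frame(
      gene = absent,
      observed_membership_number = 0L,
      observed_proportion = 0,
      expected_mean = 0, expected_sd = 0, fold_enrichment = 0,
      passes_sd_filter = FALSE, passes_membership_filter = FALSE,
      is_restored_seed = TRUE,
      stringsAsFactors = FALSE))
  }
  out$retained <- (out$passes_sd_filter & out$passes_membership_filter) |
    out$is_restored_seed
  out <- out[order(-out$fold_enrichment, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("convergence_table", class(out))
  out
}

#' Genes retained by the convergence filters
#'
#' @param convergence a `convergence_table`.
#' @param include_restored_seeds include restored seed genes (default TRUE,
#'   the expanded list; set FALSE for the strictly convergent set).
#' @return character vector of gene symbols.
#' @export
retained_genes <- function(convergence, include_restored_seeds = TRUE) {
  keep <- convergence$passes_sd_filter & convergence$passes_membership_filter
  if (include_restored_seeds) keep <- keep | convergence$is_restored_seed
  convergence$gene[keep]
}

#' Write a convergence table to TSV
#'
#' @param convergence a `convergence_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_convergence_table <- function(convergence, path)
  write_tsv(convergence, path)
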