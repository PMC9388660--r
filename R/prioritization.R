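#' Composite prioritization scores
#'
#' Scores each convergent gene on three variables — network connectivity
#' (the fold enrichment from [convergence_table()]), raw abundance in the
#' target cell type, and relative enrichment there — each normalized by
#' its maximum over the scored gene set, and sums them:
#'
#' connectivity/max(connectivity) + expression/max(expression) +
#' enrichment/max(enrichment), with a maximum composite score of 3.0.
#'
#' A gene holding the category maximum in all three variables therefore
#' scores exactly 3.0. If a category's maximum is 0 (no signal in that
#' category), all its normalized values are set to 0 with a warning.
#'
#' @param convergence a `convergence_table`.
#' @param metrics per-gene atlas metrics data.frame from [atlas_metrics()]
#'   (columns `gene`, `abundance`, `relative_enrichment`); genes missing
#'   from it score 0 in both expression categories and are flagged.
#' @param include_restored_seeds score restored seed genes too (default
#'   FALSE: only genes passing both convergence filters are scored).
#' @return data.frame of class `composite_score_table` with raw values
#'   (`connectivity_raw`, `expression_raw`, `enrichment_raw`), normalized
#'   values (`*_norm`), `composite` in [0, 3], and `atlas_missing`, sorted
#'   by composite score (ties broken alphabetically).
#' @export
composite_scores <- function(convergence, metrics,
                             include_restored_seeds = FALSE) {
  genes <- retained_genes(convergence, include_restored_seeds)
  if (!length(genes))
    stop_fatal("nothing to score: no gene passes the convergence filters")
  idx <- match(genes, convergence$gene)
  conn <- convergence$fold_enrichment[idx]

  mi <- match(genes, normalize_symbols(metrics$gene))
  expr <- ifelse(is.na(mi), 0, metrics$abundance[mi])
  enr <- ifelse(is.na(mi), 0, metrics$relative_enrichment[mi])
  expr[is.na(expr)] <- 0
  enr[is.na(enr)] <- 0

  norm <- function(x, what) {
    mx <- max(x)
    if (mx <= 0) {
      warning("composite_scores: category '", what,
              "' has no positive values; normalized scores set to 0")
      return(rep(0, length(x)))
    }
    x / mx
  }
  cn <- norm(conn, "connectivity")
  en <- norm(expr, "expression")
  rn <- norm(enr, "enrichment")

  out <- data.frame(
    gene = genes,
    connectivity_raw = conn, expression_raw = expr, enrichment_raw = enr,
    connectivity_norm = cn, expression_norm = en, enrichment_norm = rn,
    composite = cn + en + rn,
    atlas_missing = is.na(mi),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$composite, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("composite_score_table", class(out))
  out
}

#' Top-ranked targets by composite score
#'
#' Genes sorted by composite score descending, ties broken by gene symbol
#' ascending (deterministic), truncated to the first `n`.
#'
#' @param table a `composite_score_table`.
#' @param n number of targets to return (default 25).
#' @return character vector of at most `n` gene symbols in rank order.
#' @export
top_targets <- function(table, n = 25L) {
  stopifnot(n >= 1L)
  ord <- order(-table$composite, table$gene)
  head(table$gene[ord], n)
}

#' Write a composite score table to TSV
#'
#' @param table a `composite_score_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) write_tsv(table, path)
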