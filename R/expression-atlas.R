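#' Construct an expression atlas
#'
#' An expression atlas is a non-negative gene-by-cluster matrix of mean
#' expression levels (arbitrary units), e.g. Dropviz-style per-cluster
#' means from brain single-cell data. It defines which genes are "present"
#' in a target cell type, their raw abundance there, and their relative
#' enrichment versus all other clusters.
#'
#' @param values numeric matrix with genes as rows and clusters as columns;
#'   rownames and colnames are required and must be unique.
#' @return an object of class `expression_atlas` (list with `genes`,
#'   `clusters`, `values`).
#' @seealso [read_atlas()], [genes_present()], [abundance()],
#'   [relative_enrichment()]
#' @export
expression_atlas <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_fatal("atlas matrix needs gene rownames and cluster colnames")
  if (!nrow(values)) stop_fatal("atlas has no genes")
  if (!ncol(values)) stop_fatal("atlas has no clusters")
  rownames(values) <- normalize_symbols(rownames(values))
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop_fatal("duplicated gene(s) in atlas: ", paste(dup_g, collapse = ", "))
  dup_c <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_c))
    stop_fatal("duplicated cluster(s) in atlas: ",
               paste(dup_c, collapse = ", "))
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop_fatal("atlas values must be finite numbers")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_fatal("negative atlas value at gene ", rownames(values)[bad[1L]],
               ", cluster ", colnames(values)[bad[2L]])
  }
  structure(list(genes = rownames(values), clusters = colnames(values),
                 values = values),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat("expression_atlas:", length(x$genes), "genes x",
      length(x$clusters), "clusters\n")
  invisible(x)
}

#' Read an expression atlas from a delimited matrix file
#'
#' The first column holds gene symbols, the header row holds cluster
#' labels. The delimiter is inferred from the extension (`.csv` is
#' comma-delimited, everything else tab-delimited). Negative or
#' non-numeric cells and duplicated labels are fatal.
#'
#' @param path path to a TSV/CSV matrix file.
#' @return an [expression_atlas()] object with upper-cased gene symbols.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop_fatal("atlas file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stop_fatal("atlas has no genes")
  if (ncol(df) < 2L) stop_fatal("atlas has no clusters")
  genes <- as.character(df[[1L]])
  num <- df[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop_fatal("non-numeric atlas value at row ", i, " (gene ", genes[i],
                 "), column ", colnames(num)[j])
    }
    num[[j]] <- v
  }
  m <- as.matrix(num)
  rownames(m) <- genes
  expression_atlas(m)
}

check_clusters <- function(atlas, target_clusters) {
  unknown <- setdiff(target_clusters, atlas$clusters)
  if (length(unknown))
    stop_fatal("unknown cluster label(s): ", paste(unknown, collapse = ", "),
               "; valid labels: ", paste(atlas$clusters, collapse = ", "))
  if (!length(target_clusters)) stop_fatal("no target clusters given")
  target_clusters
}

#' Genes present in a set of target clusters
#'
#' A gene counts as present in the target cell type when its expression
#' strictly exceeds `min_level` in at least one target cluster. The
#' default `min_level = 0` is the most permissive reading of presence:
#' any nonzero expression.
#'
#' @param atlas an [expression_atlas()].
#' @param target_clusters character vector of cluster labels defining the
#'   target cell type.
#' @param min_level presence threshold (strict, default 0).
#' @return character vector of present gene symbols.
#' @export
genes_present <- function(atlas, target_clusters, min_level = 0) {
  target_clusters <- check_clusters(atlas, target_clusters)
  sub <- atlas$values[, target_clusters, drop = FALSE]
  atlas$genes[apply(sub > min_level, 1L, any)]
}

#' Raw abundance in the target cell type
#'
#' Arithmetic mean of a gene's expression over the target clusters. Genes
#' absent from the atlas return `NA`; downstream scoring treats them as 0
#' and flags them.
#'
#' @param atlas an [expression_atlas()].
#' @param genes character vector of gene symbols (normalized on lookup).
#' @param target_clusters target cluster labels.
#' @return named numeric vector of mean target expression, `NA` for genes
#'   not in the atlas.
#' @export
abundance <- function(atlas, genes, target_clusters) {
  target_clusters <- check_clusters(atlas, target_clusters)
  genes <- normalize_symbols(genes)
  sub <- atlas$values[, target_clusters, drop = FALSE]
  means <- rowMeans(sub)
  out <- means[match(genes, atlas$genes)]
  names(out) <- genes
  out
}

#' Relative enrichment in the target cell type
#'
#' Ratio of mean target-cluster expression to mean off-target-cluster
#' expression, each stabilized by a pseudocount so that genes expressed
#' exclusively in the target clusters get a large finite ratio. The
#' default pseudocount is 1e-6 of the atlas-wide maximum, which keeps the
#' ratio scale-invariant: rescaling all atlas values leaves it unchanged.
#'
#' @inheritParams abundance
#' @param pseudocount small positive stabilizer; default
#'   `1e-6 * max(atlas$values)`.
#' @return named numeric vector of enrichment ratios, `NA` for genes not
#'   in the atlas.
#' @export
relative_enrichment <- function(atlas, genes, target_clusters,
                                pseudocount = NULL) {
  target_clusters <- check_clusters(atlas, target_clusters)
  off <- setdiff(atlas$clusters, target_clusters)
  if (!length(off))
    stop_fatal("relative enrichment needs at least one non-target cluster")
  if (is.null(pseudocount)) pseudocount <- 1e-6 * max(atlas$values)
  if (pseudocount <= 0) pseudocount <- .Machine$double.eps
  genes <- normalize_symbols(genes)
  tmean <- rowMeans(atlas$values[, target_clusters, drop = FALSE])
  omean <- rowMeans(atlas$values[, off, drop = FALSE])
  ratio <- (tmean + pseudocount) / (omean + pseudocount)
  out <- ratio[match(genes, atlas$genes)]
  names(out) <- genes
  out
}

#' Per-gene atlas metrics table
#'
#' Convenience wrapper combining presence, abundance and relative
#' enrichment for a set of genes. Genes missing from the atlas score 0 in
#' both quantities and are flagged via `in_atlas = FALSE`.
#'
#' @inheritParams relative_enrichment
#' @param min_level presence threshold passed to [genes_present()].
#' @return data.frame with columns `gene`, `abundance`,
#'   `relative_enrichment`, `present`, `in_atlas`.
#' @export
atlas_metrics <- function(atlas, genes, target_clusters, min_level = 0,
                          pseudocount = NULL) {
  genes <- normalize_symbols(genes)
  ab <- abundance(atlas, genes, target_clusters)
  en <- relative_enrichment(atlas, genes, target_clusters, pseudocount)
  present <- genes %in% genes_present(atlas, target_clusters, min_level)
  in_atlas <- genes %in% atlas$genes
  data.frame(gene = genes,
             abundance = ifelse(in_atlas, ab, 0),
             relative_enrichment = ifelse(in_atlas, en, 0),
             present = present,
             in_atlas = in_atlas,
             stringsAsFactors = FALSE, row.names = NULL)
}
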