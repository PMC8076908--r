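#' Construct an expression batch
#'
#' Bundles one batch of single-cell expression data: a cells x genes matrix of
#' non-negative values together with gene and cell identifiers, a batch tag,
#' and (optionally) externally provided cell labels and/or cluster labels.
#'
#' @param counts Numeric matrix (or `Matrix` sparse matrix), cells in rows,
#'   genes in columns. Entries must be non-negative.
#' @param gene_ids Character vector of unique gene identifiers, one per column.
#' @param cell_ids Character vector of cell identifiers, one per row.
#' @param batch_tag Single string naming the batch.
#' @param provided_labels Optional character vector of per-cell annotations
#'   (e.g. published cell types), used by [filter_small_clusters()].
#' @param cluster_labels Optional integer vector of per-cell cluster ids
#'   (0-based), normally filled in by [louvain_cluster()].
#'
#' @return An object of class `expression_batch`.
#' @examples
#' m <- matrix(rpois(20, 2), nrow = 4,
#'             dimnames = list(NULL, paste0("g", 1:5)))
#' b <- expression_batch(m, paste0("g", 1:5), paste0("c", 1:4), "demo")
#' b
#' @export
expression_batch <- function(counts, gene_ids = colnames(counts),
                             cell_ids = rownames(counts), batch_tag,
                             provided_labels = NULL, cluster_labels = NULL) {
  if (is.null(gene_ids)) stop("gene_ids required (or name the matrix columns)")
  if (is.null(cell_ids)) cell_ids <- paste0(batch_tag, "_cell", seq_len(nrow(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (ncol(counts) != length(gene_ids))
    stop("column count must equal number of gene_ids")
  if (nrow(counts) != length(cell_ids))
    stop("row count must equal number of cell_ids")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (min(counts) < 0) stop("counts entries must be >= 0")
  if (!is.null(provided_labels) && length(provided_labels) != nrow(counts))
    stop("provided_labels must have one entry per cell")
  if (!is.null(cluster_labels) && length(cluster_labels) != nrow(counts))
    stop("cluster_labels must have one entry per cell")
  structure(list(
    counts = counts,
    gene_ids = gene_ids,
    cell_ids = cell_ids,
    batch_tag = as.character(batch_tag)[1],
    provided_labels = if (is.null(provided_labels)) NULL else as.character(provided_labels),
    cluster_labels = if (is.null(cluster_labels)) NULL else as.integer(cluster_labels)
  ), class = "expression_batch")
}

#' @export
print.expression_batch <- function(x, ...) {
  cat(sprintf("<expression_batch '%s'>: %d cells x %d genes\n",
              x$batch_tag, nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$provided_labels))
    cat("  provided labels:", length(unique(x$provided_labels)), "distinct\n")
  if (!is.null(x$cluster_labels))
    cat("  cluster labels:", length(unique(x$cluster_labels)), "clusters\n")
  invisible(x)
}

#' @export
dim.expression_batch <- function(x) dim(x$counts)

# subset a batch to cells (rows) and/or genes (cols), keeping metadata aligned
subset_batch <- function(batch, cells = NULL, genes = NULL) {
  counts <- batch$counts
  cell_ids <- batch$cell_ids
  gene_ids <- batch$gene_ids
  provided <- batch$provided_labels
  clusters <- batch$cluster_labels
  if (!is.null(cells)) {
    counts <- counts[cells, , drop = FALSE]
    cell_ids <- cell_ids[cells]
    if (!is.null(provided)) provided <- provided[cells]
    if (!is.null(clusters)) clusters <- clusters[cells]
  }
  if (!is.null(genes)) {
    counts <- counts[, genes, drop = FALSE]
    gene_ids <- gene_ids[genes]
  }
  expression_batch(counts, gene_ids, cell_ids, batch$batch_tag,
                   provided_labels = provided, cluster_labels = clusters)
}

#' Construct a feature matrix
#'
#' A per-cell feature representation (typically principal components) tied to a
#' parent [expression_batch()]. Rows align 1:1 with the parent batch's cells.
#'
#' @param values Numeric matrix, cells x k features.
#' @param source_batch Batch tag of the parent batch.
#' @param cell_ids Cell identifiers (propagated from the parent batch).
#' @param variance_ratio Optional per-component explained-variance ratios.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, source_batch, cell_ids = rownames(values),
                           variance_ratio = NULL) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(nrow(values)))
  structure(list(values = values, k = ncol(values),
                 source_batch = source_batch,
                 cell_ids = as.character(cell_ids),
                 variance_ratio = variance_ratio),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix '%s'>: %d cells x %d features\n",
              x$source_batch, nrow(x$values), x$k))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)
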