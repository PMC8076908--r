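#' Read a batch from MatrixMarket files
#'
#' Reads a sparse cells x genes (or genes x cells) count matrix in MTX format
#' with TSV sidecar files of gene ids and cell barcodes, the layout emitted by
#' the common single-cell quantifiers.
#'
#' @param mtx Path to the `.mtx` file.
#' @param genes Path to a TSV whose first column holds gene ids (one per row).
#' @param barcodes Path to a TSV whose first column holds cell barcodes.
#' @param batch_tag Name for the batch.
#' @param labels Optional path to a per-cell label file (one label per line,
#'   aligned with `barcodes`).
#' @param cells_in_rows If `FALSE` (the convention of most quantifiers) the
#'   MTX is genes x cells and is transposed on read.
#' @return An [expression_batch()].
#' @export
read_batch_mtx <- function(mtx, genes, barcodes, batch_tag,
                           labels = NULL, cells_in_rows = FALSE) {
  m <- Matrix::readMM(mtx)
  g <- utils::read.table(genes, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  b <- utils::read.table(barcodes, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (!cells_in_rows) m <- Matrix::t(m)
  lab <- if (!is.null(labels))
    utils::read.table(labels, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  expression_batch(as(m, "CsparseMatrix"), g, b, batch_tag,
                   provided_labels = lab)
}

#' Read a batch from a dense CSV
#'
#' Expects cells in rows and genes in columns, with a header row of gene ids
#' and the first column holding cell ids.
#'
#' @param path CSV file path.
#' @param batch_tag Name for the batch.
#' @param labels Optional path to a per-cell label file (one label per line).
#' @return An [expression_batch()].
#' @export
read_batch_csv <- function(path, batch_tag, labels = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cell_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  lab <- if (!is.null(labels))
    utils::read.table(labels, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  expression_batch(m, colnames(m), cell_ids, batch_tag, provided_labels = lab)
}

#' Write a feature matrix as CSV
#'
#' @param fm A [feature_matrix()].
#' @param path Output CSV path; the first column is the cell id.
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(cell_id = fm$cell_ids, fm$values, check.names = FALSE)
  colnames(df) <- c("cell_id", paste0("PC", seq_len(fm$k)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write cluster-match artefacts to a directory
#'
#' Writes the cluster distance matrix `U` and the match map as CSV, the
#' cross-batch weight matrix `M` and the within-batch indicator matrices
#' `C1`/`C2` as sparse MatrixMarket files, and per-batch cluster labels as
#' two-column CSVs.
#'
#' @param cm A [cluster_match()] object.
#' @param dir Output directory (created if missing).
#' @export
write_cluster_match <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cm$U, file.path(dir, "U.csv"), row.names = FALSE)
  utils::write.csv(data.frame(batch1_cluster = seq_along(cm$match) - 1L,
                              batch2_cluster = cm$match),
                   file.path(dir, "match.csv"), row.names = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(cm$M, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "M.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(cm$C1, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "C1.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(cm$C2, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "C2.mtx"))
  utils::write.csv(data.frame(cell_id = cm$cell_ids1, cluster = cm$labels1),
                   file.path(dir, "clusters_batch1.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = cm$cell_ids2, cluster = cm$labels2),
                   file.path(dir, "clusters_batch2.csv"), row.names = FALSE)
  invisible(dir)
}
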