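#' Drop cells belonging to small annotated clusters
#'
#' Cells whose provided label occurs in fewer than `min_cells` cells are
#' removed; tiny populations destabilise the downstream cluster matching and
#' the prediction loss. Cell order is otherwise preserved.
#'
#' @param batch An [expression_batch()] with `provided_labels` set.
#' @param min_cells Minimum cluster size to retain (default 10); a label is
#'   kept when its cell count is `>= min_cells`.
#' @return The filtered [expression_batch()].
#' @export
filter_small_clusters <- function(batch, min_cells = 10) {
  if (is.null(batch$provided_labels))
    stop("annotation required: batch has no provided_labels")
  tab <- table(batch$provided_labels)
  keep_labels <- names(tab)[tab >= min_cells]
  keep <- batch$provided_labels %in% keep_labels
  subset_batch(batch, cells = which(keep))
}

#' Filter genes by expression prevalence in both batches
#'
#' First intersects the gene sets of the two batches, then keeps genes
#' expressed (count > 0) in at least `min_cells_1` cells of batch 1 and
#' `min_cells_2` cells of batch 2. Both outputs share one ordered gene list.
#'
#' @param b1,b2 [expression_batch()] objects.
#' @param min_cells_1,min_cells_2 Per-batch prevalence thresholds. Typical
#'   values: 50 for a few-thousand-cell batch, 100 for larger collections.
#' @return List of the two filtered batches, `list(b1 = , b2 = )`.
#' @export
filter_genes <- function(b1, b2, min_cells_1 = 50, min_cells_2 = 50) {
  shared <- intersect(b1$gene_ids, b2$gene_ids)
  if (length(shared) == 0) stop("no shared genes between batches")
  i1 <- match(shared, b1$gene_ids)
  i2 <- match(shared, b2$gene_ids)
  n1 <- Matrix::colSums(b1$counts[, i1, drop = FALSE] > 0)
  n2 <- Matrix::colSums(b2$counts[, i2, drop = FALSE] > 0)
  keep <- n1 >= min_cells_1 & n2 >= min_cells_2
  list(b1 = subset_batch(b1, genes = i1[keep]),
       b2 = subset_batch(b2, genes = i2[keep]))
}

#' Total-count normalization and log transform
#'
#' Each cell's counts are scaled to a common total (`scale`, default 1e4) and
#' log-transformed: value = ln(count / cell_total * scale + 1). Totals are the
#' per-cell sums over the current (post-filtering) gene set.
#'
#' @param batch An [expression_batch()].
#' @param scale Target total count per cell.
#' @return The normalized [expression_batch()].
#' @export
normalize_log <- function(batch, scale = 1e4) {
  totals <- Matrix::rowSums(batch$counts)
  if (any(totals == 0)) stop("empty cell: a cell has zero total count")
  norm <- as.matrix(batch$counts / totals) * scale
  out <- batch
  out$counts <- log1p(norm)
  out
}

#' Select highly variable genes jointly across two batches
#'
#' Dispersion-based selection on the concatenated normalized batches, using
#' the standard recipe: dispersion = variance/mean of the de-logged values,
#' genes binned into 20 equal-frequency mean bins, dispersions z-scored within
#' each bin, and a gene kept when `min_mean < mean < max_mean` and its
#' normalized dispersion exceeds `min_disp`. A single subset is returned so
#' both batches stay on one feature space.
#'
#' @param b1,b2 Normalized batches on an identical gene set.
#' @param min_mean,max_mean,min_disp Selection cutoffs (reference defaults
#'   0.0125, 3, 0.5).
#' @param n_top If given, overrides the cutoffs and keeps the `n_top` genes
#'   with the highest normalized dispersion (ties broken by gene order).
#' @param n_bins Number of mean bins (default 20).
#' @return Character vector of selected gene ids, in original gene order.
#' @export
select_hvg <- function(b1, b2, min_mean = 0.0125, max_mean = 3,
                       min_disp = 0.5, n_top = NULL, n_bins = 20) {
  if (!identical(b1$gene_ids, b2$gene_ids))
    stop("batches must share an identical ordered gene set")
  x <- rbind(as.matrix(b1$counts), as.matrix(b2$counts))
  if (ncol(x) < 2) stop("need at least 2 genes for HVG selection")
  ex <- expm1(x)                      # back to the normalized count scale
  mu <- colMeans(ex)
  v <- apply(ex, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency bins on the mean; z-score dispersion within each bin
  brk <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = brk, include.lowest = TRUE)
  disp_norm <- disp
  for (lv in levels(bin)) {
    idx <- which(bin == lv)
    m <- mean(disp[idx]); s <- stats::sd(disp[idx])
    if (!is.finite(s) || s == 0) s <- 1
    disp_norm[idx] <- (disp[idx] - m) / s
  }
  if (!is.null(n_top)) {
    ord <- order(-disp_norm, seq_along(disp_norm))
    keep <- sort(ord[seq_len(min(n_top, length(ord)))])
  } else {
    keep <- which(mu > min_mean & mu < max_mean & disp_norm > min_disp)
  }
  if (length(keep) < 2) stop("fewer than 2 highly variable genes selected")
  b1$gene_ids[keep]
}

#' Joint PCA embedding of two batches
#'
#' Fits PCA on the vertically stacked cells of both batches (per-gene
#' centering, no scaling) so that both batches live in one principal-component
#' space, and returns the top `k` scores per batch plus the explained-variance
#' ratios.
#'
#' @param b1,b2 Normalized, HVG-restricted batches on the same gene set.
#' @param k Number of components to retain.
#' @return List with `f1`, `f2` ([feature_matrix()] objects) and
#'   `variance_ratio` (all components, non-increasing).
#' @export
pca_embed <- function(b1, b2, k) {
  if (!identical(b1$gene_ids, b2$gene_ids))
    stop("batches must share an identical ordered gene set")
  x <- rbind(as.matrix(b1$counts), as.matrix(b2$counts))
  if (k > min(dim(x))) stop("k exceeds min(cells, genes)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vr <- pc$sdev^2 / sum(pc$sdev^2)
  n1 <- nrow(b1$counts)
  s <- pc$x[, seq_len(k), drop = FALSE]
  list(f1 = feature_matrix(s[seq_len(n1), , drop = FALSE],
                           b1$batch_tag, b1$cell_ids, vr[seq_len(k)]),
       f2 = feature_matrix(s[-seq_len(n1), , drop = FALSE],
                           b2$batch_tag, b2$cell_ids, vr[seq_len(k)]),
       variance_ratio = vr)
}

#' Choose the number of principal components at the scree elbow
#'
#' Locates the bending point of the explained-variance curve as the index
#' maximizing the second difference (discrete curvature) of the variance
#' ratios, and returns the candidate value closest to it. Ties go to the
#' smaller index / smaller candidate, so a flat scree yields the smallest
#' candidate.
#'
#' @param variance_ratios Non-increasing per-component explained-variance
#'   ratios.
#' @param candidates Candidate values of k (default `c(10, 15, 20, 25, 30)`).
#' @return One element of `candidates`.
#' @examples
#' r <- c(rep(0.1, 5), 0.02 * 0.9^(0:19))
#' choose_k(r / sum(r), c(3, 5, 8))
#' @export
choose_k <- function(variance_ratios, candidates = c(10, 15, 20, 25, 30)) {
  if (length(candidates) == 0) stop("candidates must be non-empty")
  r <- as.numeric(variance_ratios)
  if (length(r) < 3) return(candidates[1])
  i <- 2:(length(r) - 1)
  curv <- r[i - 1] - 2 * r[i] + r[i + 1]
  elbow <- i[which.max(curv)]          # which.max takes the first maximum
  candidates[which.min(abs(candidates - elbow))]
}

#' Run the full preprocessing chain on a pair of batches
#'
#' Applies, in order: small-cluster cell filtering (when annotations are
#' present), prevalence-based gene filtering on the shared gene set,
#' total-count log normalization, joint highly-variable-gene selection, and
#' joint PCA. The number of components is chosen at the scree elbow unless
#' `n_pcs` is given.
#'
#' @param b1,b2 Raw-count [expression_batch()] objects.
#' @param min_cluster_cells Small-cluster threshold (applied only when
#'   `provided_labels` exist).
#' @param min_cells_per_gene Length-2 prevalence thresholds for the two
#'   batches (recycled if length 1).
#' @param scale Normalization target total.
#' @param n_pcs Number of PCs; `NULL` picks it with [choose_k()].
#' @param k_candidates Candidate PC numbers for [choose_k()].
#' @param hvg Arguments forwarded to [select_hvg()] as a list.
#' @return List with feature matrices `f1`, `f2`, the normalized HVG-restricted
#'   batches `nb1`, `nb2`, `hvg_genes`, `n_pcs` and `variance_ratio`.
#' @export
preprocess_batches <- function(b1, b2, min_cluster_cells = 10,
                               min_cells_per_gene = c(50, 50), scale = 1e4,
                               n_pcs = NULL, k_candidates = c(10, 15, 20, 25, 30),
                               hvg = list()) {
  if (length(min_cells_per_gene) == 1)
    min_cells_per_gene <- rep(min_cells_per_gene, 2)
  if (!is.null(b1$provided_labels))
    b1 <- filter_small_clusters(b1, min_cluster_cells)
  if (!is.null(b2$provided_labels))
    b2 <- filter_small_clusters(b2, min_cluster_cells)
  fg <- filter_genes(b1, b2, min_cells_per_gene[1], min_cells_per_gene[2])
  nb1 <- normalize_log(fg$b1, scale)
  nb2 <- normalize_log(fg$b2, scale)
  hvg_genes <- do.call(select_hvg, c(list(nb1, nb2), hvg))
  gi <- match(hvg_genes, nb1$gene_ids)
  nb1 <- subset_batch(nb1, genes = gi)
  nb2 <- subset_batch(nb2, genes = gi)
  kmax <- if (is.null(n_pcs)) max(k_candidates) else n_pcs
  kmax <- min(kmax, nrow(nb1$counts) + nrow(nb2$counts), length(hvg_genes))
  pe <- pca_embed(nb1, nb2, kmax)
  k <- if (is.null(n_pcs)) {
    k <- choose_k(pe$variance_ratio, k_candidates[k_candidates <= kmax])
  } else n_pcs
  f1 <- feature_matrix(pe$f1$values[, seq_len(k), drop = FALSE],
                       nb1$batch_tag, nb1$cell_ids, pe$variance_ratio[seq_len(k)])
  f2 <- feature_matrix(pe$f2$values[, seq_len(k), drop = FALSE],
                       nb2$batch_tag, nb2$cell_ids, pe$variance_ratio[seq_len(k)])
  list(f1 = f1, f2 = f2, nb1 = nb1, nb2 = nb2, hvg_genes = hvg_genes,
       n_pcs = k, variance_ratio = pe$variance_ratio)
}
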