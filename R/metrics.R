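#' kBET-style batch-mixing rejection rate
#'
#' For every cell, a chi-square goodness-of-fit test compares the batch
#' composition of its k-nearest neighbourhood (the cell included) with the
#' global batch proportions. The returned value is the fraction of cells whose
#' test rejects at level `alpha`: near `alpha` for well-mixed batches, near 1
#' for separated ones.
#'
#' @param embedding Numeric matrix, cells x dimensions.
#' @param batch_tags Per-cell batch labels (>= 2 distinct).
#' @param k Neighbourhood size; default `min(25, floor(0.1 * n))`.
#' @param alpha Significance level (default 0.05).
#' @return Rejection rate in `[0, 1]`.
#' @export
kbet_rejection <- function(embedding, batch_tags, k = NULL, alpha = 0.05) {
  x <- as.matrix(embedding)
  n <- nrow(x)
  tags <- as.character(batch_tags)
  lv <- sort(unique(tags))
  if (length(lv) < 2) stop("metric undefined: need at least 2 batches")
  if (is.null(k)) k <- min(25, floor(0.1 * n))
  if (k >= n) stop("k must be smaller than the number of cells")
  props <- as.numeric(table(factor(tags, lv))) / n
  nn <- knn_index(x, k - 1L)                 # self completes the neighbourhood
  tag_id <- base::match(tags, lv)
  crit <- stats::qchisq(1 - alpha, df = length(lv) - 1)
  rejected <- vapply(seq_len(n), function(i) {
    ids <- c(i, nn[i, ])
    obs <- tabulate(tag_id[ids], nbins = length(lv))
    expd <- k * props
    sum((obs - expd)^2 / expd) > crit
  }, logical(1))
  mean(rejected)
}

#' Mean silhouette score
#'
#' Per-cell `(b - a) / max(a, b)` with `a` the mean intra-label Euclidean
#' distance and `b` the smallest mean distance to another label, averaged.
#'
#' @param embedding Numeric matrix, cells x dimensions.
#' @param labels Per-cell labels (>= 2 distinct).
#' @return Scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(embedding, labels) {
  f <- as.integer(factor(labels))
  if (length(unique(f)) < 2) stop("silhouette undefined for a single label")
  sil <- cluster::silhouette(f, stats::dist(as.matrix(embedding)))
  mean(sil[, "sil_width"])
}

# pair-counting contingency machinery shared by ARI and FMI
pair_counts <- function(a, b) {
  ct <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  list(TP = sum_ij, pairs_a = sum_a, pairs_b = sum_b,
       total = choose(n, 2))
}

#' Adjusted Rand index
#'
#' Rand index corrected for chance agreement under the hypergeometric model
#' of random labelings with fixed marginals.
#'
#' @param labels_a,labels_b Two labelings of the same cells.
#' @return Scalar `<= 1`; 0 expected under independence.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("labelings differ in length")
  pc <- pair_counts(labels_a, labels_b)
  expected <- pc$pairs_a * pc$pairs_b / pc$total
  max_idx <- (pc$pairs_a + pc$pairs_b) / 2
  if (max_idx == expected) return(1)        # both labelings trivial/identical
  (pc$TP - expected) / (max_idx - expected)
}

#' Normalized mutual information
#'
#' Mutual information between two labelings normalized by the arithmetic mean
#' of their entropies. When both labelings are constant the value is defined
#' as 1; when exactly one is constant, 0.
#'
#' @param labels_a,labels_b Two labelings of the same cells.
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("labelings differ in length")
  n <- length(labels_a)
  ct <- table(labels_a, labels_b) / n
  pa <- rowSums(ct); pb <- colSums(ct)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- ct > 0
  mi <- sum(ct[nz] * log(ct[nz] / (pa[row(ct)[nz]] * pb[col(ct)[nz]])))
  mi / ((ha + hb) / 2)
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pairwise precision and recall over same-cluster pairs:
#' `TP / sqrt((TP + FP) * (TP + FN))`. Defined as 0 when either labeling has
#' no same-cluster pair.
#'
#' @param labels_a,labels_b Two labelings of the same cells.
#' @return Scalar in `[0, 1]`.
#' @export
fmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("labelings differ in length")
  pc <- pair_counts(labels_a, labels_b)
  if (pc$pairs_a == 0 || pc$pairs_b == 0) return(0)
  pc$TP / sqrt(pc$pairs_a * pc$pairs_b)
}

#' Evaluate an aligned embedding
#'
#' Computes the five integration metrics for one embedding: the kBET
#' rejection rate on batch mixing; the silhouette of a fresh Louvain
#' clustering of the embedding (how well the aligned data clusters); and
#' NMI/ARI/FMI between that clustering and the original per-batch cluster
#' labels, each computed within its batch and averaged over the two batches.
#'
#' @param embedding Matrix of aligned coordinates, batch-1 cells first.
#' @param batch_tags Per-cell batch labels.
#' @param labels1,labels2 Original cluster labels of the two batches.
#' @param resolution,seed,n_neighbors Passed to [louvain_cluster()] for the
#'   joint clustering.
#' @param k,alpha kBET parameters.
#' @return Object of class `evaluation_report` (also a plain list of the five
#'   metrics plus the parameters used).
#' @export
evaluate_alignment <- function(embedding, batch_tags, labels1, labels2,
                               resolution = 1, seed = 0, n_neighbors = 15,
                               k = NULL, alpha = 0.05) {
  tags <- as.character(batch_tags)
  lv <- unique(tags)
  stopifnot(length(lv) == 2)
  joint <- louvain_cluster(embedding, resolution, seed, n_neighbors)
  in1 <- tags == lv[1]; in2 <- tags == lv[2]
  stopifnot(sum(in1) == length(labels1), sum(in2) == length(labels2))
  per_batch <- function(f) (f(joint[in1], labels1) + f(joint[in2], labels2)) / 2
  structure(list(
    kbet_rejection = kbet_rejection(embedding, tags, k, alpha),
    silhouette = silhouette_score(embedding, joint),
    nmi = per_batch(nmi),
    ari = per_batch(ari),
    fmi = per_batch(fmi),
    joint_labels = joint,
    params = list(k = k, alpha = alpha, resolution = resolution,
                  label_sources = "joint Louvain vs per-batch clusters")
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  kBET rejection: %.3f\n", x$kbet_rejection))
  cat(sprintf("  silhouette:     %.3f\n", x$silhouette))
  cat(sprintf("  NMI:            %.3f\n", x$nmi))
  cat(sprintf("  ARI:            %.3f\n", x$ari))
  cat(sprintf("  FMI:            %.3f\n", x$fmi))
  invisible(x)
}
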