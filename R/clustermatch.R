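#' Louvain clustering on a kNN graph
#'
#' Builds an (exact) k-nearest-neighbour graph on the feature space with
#' Euclidean distances and partitions it by Louvain modularity optimization.
#' Labels are contiguous integers starting at 0, ordered by first occurrence,
#' and are deterministic for a fixed seed.
#'
#' @param features A [feature_matrix()] or a plain numeric matrix.
#' @param resolution Louvain resolution (default 1; larger values give more
#'   clusters).
#' @param seed Integer seed for the community detection.
#' @param n_neighbors Neighbourhood size for the graph (default 15).
#' @return Integer vector of per-cell cluster labels (0-based).
#' @export
louvain_cluster <- function(features, resolution = 1, seed = 0,
                            n_neighbors = 15) {
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 cells to cluster")
  if (n <= n_neighbors) stop("fewer cells than the neighbourhood size")
  nn <- knn_index(x, n_neighbors)
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  relabel_contiguous(igraph::membership(comm))
}

# exact kNN (excluding self) by brute force; fine at the scales handled here
knn_index <- function(x, k) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  diag(d2) <- Inf
  t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
}

relabel_contiguous <- function(labels) {
  f <- match(labels, unique(labels)) - 1L
  as.integer(f)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Cosine distance between two vectors
#'
#' `1 - (u . v) / (||u|| ||v||)`, the angular dissimilarity of two expression
#' vectors, in `[0, 2]`.
#'
#' @param u,v Numeric vectors of equal length with nonzero norm.
#' @return A scalar in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined angle: zero-norm vector")
  1 - sum(u * v) / (nu * nv)
}

# all pairwise cosine distances between rows of x1 and rows of x2
cosine_distance_matrix <- function(x1, x2) {
  n1 <- sqrt(rowSums(x1^2)); n2 <- sqrt(rowSums(x2^2))
  if (any(n1 == 0) || any(n2 == 0)) stop("undefined angle: zero-norm vector")
  1 - tcrossprod(x1 / n1, x2 / n2)
}

#' Cross-batch cluster distance matrix
#'
#' For every cluster pair (i of batch 1, j of batch 2), the log10 of the mean
#' cosine distance over all cross-batch cell pairs. The log emphasises small
#' distances; means are floored at `eps` before the log so an exact-zero mean
#' stays finite.
#'
#' @param f1,f2 [feature_matrix()] objects (or matrices).
#' @param labels1,labels2 0-based integer cluster labels covering all cells.
#' @param eps Floor applied to the mean distance before log10 (default 1e-12).
#' @return Matrix `U` of size K1 x K2.
#' @export
cluster_distance_matrix <- function(f1, labels1, f2, labels2, eps = 1e-12) {
  x1 <- if (inherits(f1, "feature_matrix")) f1$values else as.matrix(f1)
  x2 <- if (inherits(f2, "feature_matrix")) f2$values else as.matrix(f2)
  stopifnot(length(labels1) == nrow(x1), length(labels2) == nrow(x2))
  k1 <- sort(unique(labels1)); k2 <- sort(unique(labels2))
  dmat <- cosine_distance_matrix(x1, x2)
  U <- matrix(NA_real_, length(k1), length(k2),
              dimnames = list(paste0("b1_", k1), paste0("b2_", k2)))
  for (a in seq_along(k1)) {
    ra <- labels1 == k1[a]
    for (b in seq_along(k2)) {
      m <- mean(dmat[ra, labels2 == k2[b], drop = FALSE])
      U[a, b] <- log10(max(m, eps))
    }
  }
  U
}

#' Match batch-1 clusters to batch-2 clusters
#'
#' Each batch-1 cluster i is matched to the batch-2 cluster with the minimum
#' distance `U[i, j]`. The map is directional and may be non-injective;
#' batch-2 clusters hit by no i remain unmatched (the missing-cell-type case).
#' Ties break to the lowest column index.
#'
#' @param U Cluster distance matrix from [cluster_distance_matrix()].
#' @return Integer vector of length K1: 0-based batch-2 cluster index per
#'   batch-1 cluster.
#' @export
match_clusters <- function(U) {
  if (length(U) == 0) stop("empty cluster distance matrix")
  if (!all(is.finite(U))) stop("U must be finite")
  as.integer(apply(U, 1, which.min) - 1L)
}

#' Within-batch same-cluster indicator matrix
#'
#' `C[p, q] = 1` iff cells p and q carry the same cluster label; symmetric with
#' unit diagonal.
#'
#' @param labels Per-cell cluster labels.
#' @return Binary n x n matrix.
#' @export
intra_batch_matrix <- function(labels) {
  outer(labels, labels, "==") * 1
}

#' Cross-batch matched-cluster weight matrix
#'
#' For cell p of batch-1 cluster i and cell q of batch-2 cluster j the weight
#' is zero unless j is i's matched cluster. For matched pairs the weight is
#' `M1 * M2`, where `M1` is the 0-1 (min-max) normalization of `-U[i, match(i)]`
#' across matched cluster pairs (closer clusters weigh more) and `M2` is
#' `1 - minmax(euclidean(p, q))` over all matched cell pairs (more similar
#' cells weigh more). When all matched values coincide the normalization
#' degenerates and the corresponding factor is 1. Matched-pair factors are
#' floored at `weight_floor` so every matched pair keeps a strictly positive
#' weight (a zero entry means, by definition, a non-matched pair).
#'
#' @param f1,f2 Feature matrices.
#' @param labels1,labels2 Per-cell cluster labels (0-based).
#' @param U Cluster distance matrix.
#' @param match Match map from [match_clusters()].
#' @param weight_floor Lower bound on the two normalized factors for matched
#'   pairs (default 0.01).
#' @return Non-negative n1 x n2 matrix `M`.
#' @export
inter_batch_weight_matrix <- function(f1, labels1, f2, labels2, U, match,
                                      weight_floor = 0.01) {
  x1 <- if (inherits(f1, "feature_matrix")) f1$values else as.matrix(f1)
  x2 <- if (inherits(f2, "feature_matrix")) f2$values else as.matrix(f2)
  k1 <- sort(unique(labels1)); k2 <- sort(unique(labels2))
  n1 <- nrow(x1); n2 <- nrow(x2)
  M <- matrix(0, n1, n2)
  if (length(match) == 0) return(M)
  # cluster-level closeness weights: min-max of -U[i, match(i)]
  v <- -U[cbind(seq_along(match), match + 1L)]
  w <- if (diff(range(v)) == 0) rep(1, length(v))
       else pmax((v - min(v)) / (max(v) - min(v)), weight_floor)
  # mask of matched cell pairs
  cl1 <- base::match(labels1, k1)                  # row index of each cell's cluster
  j_of_cell1 <- match[cl1]                         # matched batch-2 cluster id
  matched_pair <- outer(j_of_cell1, labels2, "==")
  if (!any(matched_pair)) return(M)
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  d <- sqrt(pmax(d2, 0))
  dm <- d[matched_pair]
  M2 <- if (diff(range(dm)) == 0) matrix(1, n1, n2)
        else pmax(1 - (d - min(dm)) / (max(dm) - min(dm)), weight_floor)
  M1 <- matrix(w[cl1], n1, n2)
  M <- M1 * M2
  M[!matched_pair] <- 0
  M
}

#' Cluster both batches and build the cross-batch match
#'
#' Runs [louvain_cluster()] on each batch, computes the cluster distance
#' matrix, the directional match map, the within-batch indicator matrices and
#' the cross-batch weight matrix, and bundles them.
#'
#' @param f1,f2 [feature_matrix()] objects.
#' @param resolution Louvain resolution (single value or length-2 per batch).
#' @param seed Seed for the clustering.
#' @param n_neighbors kNN graph size.
#' @param labels1,labels2 Optional pre-computed cluster labels; when supplied
#'   the Louvain step is skipped for that batch.
#' @return Object of class `cluster_match` with fields `U`, `match`, `C1`,
#'   `C2`, `M`, `labels1`, `labels2`, `K1`, `K2`, `cluster_sizes1/2`.
#' @export
cluster_match <- function(f1, f2, resolution = 1, seed = 0, n_neighbors = 15,
                          labels1 = NULL, labels2 = NULL) {
  if (length(resolution) == 1) resolution <- rep(resolution, 2)
  if (is.null(labels1))
    labels1 <- louvain_cluster(f1, resolution[1], seed, n_neighbors)
  if (is.null(labels2))
    labels2 <- louvain_cluster(f2, resolution[2], seed + 1, n_neighbors)
  U <- cluster_distance_matrix(f1, labels1, f2, labels2)
  mm <- match_clusters(U)
  structure(list(
    U = U, match = mm,
    C1 = intra_batch_matrix(labels1),
    C2 = intra_batch_matrix(labels2),
    M = inter_batch_weight_matrix(f1, labels1, f2, labels2, U, mm),
    labels1 = labels1, labels2 = labels2,
    K1 = nrow(U), K2 = ncol(U),
    cluster_sizes1 = as.integer(table(labels1)),
    cluster_sizes2 = as.integer(table(labels2)),
    cell_ids1 = if (inherits(f1, "feature_matrix")) f1$cell_ids else NULL,
    cell_ids2 = if (inherits(f2, "feature_matrix")) f2$cell_ids else NULL
  ), class = "cluster_match")
}

#' @export
print.cluster_match <- function(x, ...) {
  cat(sprintf("<cluster_match>: %d batch-1 clusters, %d batch-2 clusters\n",
              x$K1, x$K2))
  unmatched <- setdiff(seq_len(x$K2) - 1L, x$match)
  cat("  match (b1 -> b2):", paste(seq_len(x$K1) - 1L, "->", x$match,
                                   collapse = ", "), "\n")
  if (length(unmatched))
    cat("  unmatched batch-2 clusters:", paste(unmatched, collapse = ", "), "\n")
  invisible(x)
}
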