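# independent brute-force oracles, written naively on purpose
oracle_cosd <- function(u, v) 1 - sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
oracle_U <- function(x1, l1, x2, l2, eps = 1e-12) {
  k1 <- sort(unique(l1)); k2 <- sort(unique(l2))
  U <- matrix(0, length(k1), length(k2))
  for (a in seq_along(k1)) for (b in seq_along(k2)) {
    tot <- 0; cnt <- 0
    for (p in which(l1 == k1[a])) for (q in which(l2 == k2[b])) {
      tot <- tot + oracle_cosd(x1[p, ], x2[q, ]); cnt <- cnt + 1
    }
    U[a, b] <- log10(max(tot / cnt, eps))
  }
  U
}

test_that("cosine distance matches closed forms and rejects zero vectors", {
  expect_equal(cosine_distance(c(2, 1), c(2, 1)), 0, tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("cluster distance matrix U equals the brute-force double loop", {
  for (seed in 1:3) {
    set.seed(seed)
    n1 <- sample(10:50, 1); n2 <- sample(10:50, 1); d <- sample(2:8, 1)
    x1 <- matrix(rnorm(n1 * d), n1, d); x2 <- matrix(rnorm(n2 * d), n2, d)
    l1 <- sample(0:2, n1, replace = TRUE); l2 <- sample(0:3, n2, replace = TRUE)
    U <- cluster_distance_matrix(x1, l1, x2, l2)
    expect_equal(unname(U), oracle_U(x1, l1, x2, l2), tolerance = 1e-8)
  }
  # singleton clusters with a known cosine distance of 0.1
  u <- c(1, 0); v <- c(0.9, sqrt(1 - 0.81))
  U <- cluster_distance_matrix(rbind(u), 0L, rbind(v), 0L)
  expect_equal(U[1, 1], log10(0.1), tolerance = 1e-10)
  # orthogonal vectors: all cross distances 1, U = 0
  U0 <- cluster_distance_matrix(rbind(c(1, 0), c(1, 0)), c(0L, 0L),
                                rbind(c(0, 1), c(0, 2)), c(0L, 0L))
  expect_equal(U0[1, 1], 0)
})

test_that("matching is row-wise argmin with documented tie-break", {
  U <- matrix(c(-2, 0, 0, 0, -2, 0, 0, 0, -2), 3, 3)
  expect_equal(match_clusters(U), c(0L, 1L, 2L))
  expect_equal(match_clusters(matrix(c(-0.5, -2, -1), 1, 3)), 1L)
  expect_equal(match_clusters(matrix(c(-1, -1), 1, 2)), 0L)  # tie -> lowest
  # non-injective maps are allowed
  U2 <- matrix(c(-3, -3, 0, 0, 0, 0), 2, 3)
  expect_equal(match_clusters(U2), c(0L, 0L))
  expect_error(match_clusters(matrix(numeric(0), 0, 0)), "empty")
  expect_error(match_clusters(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("within-batch indicator matrices follow labels and relabeling", {
  expect_equal(intra_batch_matrix(c(0, 0, 1)),
               matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3))
  expect_equal(intra_batch_matrix(rep(2, 4)), matrix(1, 4, 4))
  expect_equal(intra_batch_matrix(1:4), diag(4))
  set.seed(7)
  l <- sample(0:3, 25, replace = TRUE)
  perm_ids <- sample(0:3)                   # relabel clusters, keep cells
  expect_equal(intra_batch_matrix(l), intra_batch_matrix(perm_ids[l + 1]))
  C <- intra_batch_matrix(l)
  expect_equal(C, t(C))
  expect_equal(diag(C), rep(1, 25))
})

test_that("M is positive exactly on matched cluster pairs", {
  set.seed(8)
  r1 <- random_features(30, 4, 3, seed = 8)
  r2 <- random_features(35, 4, 4, seed = 9)
  U <- cluster_distance_matrix(r1$x, r1$labels, r2$x, r2$labels)
  mm <- match_clusters(U)
  M <- inter_batch_weight_matrix(r1$x, r1$labels, r2$x, r2$labels, U, mm)
  k1 <- sort(unique(r1$labels))
  matched <- outer(mm[match(r1$labels, k1)], r2$labels, "==")
  expect_true(all(M[!matched] == 0))
  expect_true(all(M[matched] > 0))
  expect_true(all(M >= 0))
  # identical cells in a matched pair carry the maximal weight of their cluster pair
  x2 <- r2$x; x2[1, ] <- r1$x[which(mm[match(r1$labels, k1)] == r2$labels[1])[1], ]
  M2 <- inter_batch_weight_matrix(r1$x, r1$labels, x2, r2$labels, U, mm)
  p <- which(mm[match(r1$labels, k1)] == r2$labels[1])[1]
  expect_equal(M2[p, 1], max(M2[, 1]))
})

test_that("removing a batch-1 cluster never creates spurious matches", {
  set.seed(9)
  r1 <- random_features(40, 5, 3, seed = 10)
  r2 <- random_features(40, 5, 3, seed = 11)
  U <- cluster_distance_matrix(r1$x, r1$labels, r2$x, r2$labels)
  mm <- match_clusters(U)
  # drop the batch-1 cluster matched to batch-2 cluster j0, uniquely
  j0 <- mm[1]
  solely <- sum(mm == j0) == 1
  keep <- r1$labels != 0
  U2 <- cluster_distance_matrix(r1$x[keep, ], r1$labels[keep], r2$x, r2$labels)
  mm2 <- match_clusters(U2)
  M2 <- inter_batch_weight_matrix(r1$x[keep, ], r1$labels[keep], r2$x,
                                  r2$labels, U2, mm2)
  if (solely && !(j0 %in% mm2)) {
    expect_true(all(M2[, r2$labels == j0] == 0))
  }
  # invariant regardless: zeros exactly off the matched pairs
  k1 <- sort(unique(r1$labels[keep]))
  matched <- outer(mm2[match(r1$labels[keep], k1)], r2$labels, "==")
  expect_true(all(M2[!matched] == 0))
})

test_that("Louvain recovers well-separated blobs deterministically", {
  bl <- blob_features(n_per = 100, sep = 20, seed = 12)
  lab <- louvain_cluster(bl$x, resolution = 0.5, seed = 5)
  expect_equal(sort(unique(lab)), 0:(max(lab)))
  expect_equal(ari(lab, bl$labels), 1)
  lab2 <- louvain_cluster(bl$x, resolution = 0.5, seed = 5)
  expect_identical(lab, lab2)
  expect_error(louvain_cluster(bl$x[1:10, ], n_neighbors = 15), "fewer cells")
})

test_that("higher resolution does not coarsen the partition of a fixed graph", {
  set.seed(13)
  x <- matrix(rnorm(150 * 4), 150, 4) +
    3 * matrix(rep(sample(0:2, 150, replace = TRUE), 4), ncol = 4)
  k_lo <- length(unique(louvain_cluster(x, resolution = 0.3, seed = 1)))
  k_hi <- length(unique(louvain_cluster(x, resolution = 2.5, seed = 1)))
  expect_gte(k_hi, k_lo)
})

test_that("cluster_match bundles consistent components", {
  bl1 <- blob_features(60, sep = 15, seed = 14)
  bl2 <- blob_features(60, sep = 15, seed = 15)
  cm <- cluster_match(feature_matrix(bl1$x, "b1"), feature_matrix(bl2$x, "b2"),
                      seed = 2)
  expect_s3_class(cm, "cluster_match")
  expect_equal(dim(cm$U), c(cm$K1, cm$K2))
  expect_equal(dim(cm$M), c(nrow(bl1$x), nrow(bl2$x)))
  expect_equal(cm$C1, t(cm$C1))
  expect_equal(diag(cm$C2), rep(1, nrow(bl2$x)))
  expect_length(cm$match, cm$K1)
})
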