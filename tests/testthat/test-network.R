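# naive re-implementations of the four loss formulas (single quadruple),
# kept deliberately independent of the package code paths
naive_lr <- function(a, c, b, d, E2, F2, er) {
  sum((c(a, c) - E2)^2) / (2 * er) + sum((c(b, d) - F2)^2) / (2 * er)
}
naive_ls <- function(A4, C4, B4, D4, c1, c2, es) {
  sum((A4 - C4)^2) * c1 / es + sum((B4 - D4)^2) * c2 / es
}
naive_lc <- function(A4, B4, C4, D4, mab, mcd, ec) {
  sum((A4 - B4)^2) * mab / ec + sum((C4 - D4)^2) * mcd / ec
}
naive_lp <- function(ps, ys) {
  tot <- 0
  for (i in 1:4) tot <- tot + sum((ps[[i]] - ys[[i]])^2) / length(ps[[i]])
  tot
}
rand_simplex <- function(k) { e <- rexp(k); e / sum(e) }

test_that("forward pass honours shapes, determinism and stream symmetry", {
  net <- paired_autoencoder(4, hidden_dims = 6, embed_dim = 3,
                            n_classes_b1 = 2, n_classes_b2 = 3, seed = 1)
  set.seed(2)
  a <- rnorm(4); b <- rnorm(4); c <- rnorm(4); d <- rnorm(4)
  fw <- forward_pair(net, a, b, c, d)
  expect_equal(dim(fw$A4), c(1, 4))
  expect_equal(dim(fw$Mvec), c(1, 3))
  expect_equal(dim(fw$E2), c(1, 8))
  expect_equal(rowSums(fw$class_probs$A), 1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowSums(fw$class_probs$D), 1, tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical inputs in both streams give identical outputs (shared weights)
  fw2 <- forward_pair(net, a, b, a, b)
  expect_equal(fw2$Mvec, fw2$Nvec)
  expect_equal(fw2$A4, fw2$C4)
  # determinism
  expect_equal(forward_pair(net, a, b, c, d)$E2, fw$E2)
  expect_error(forward_pair(net, rnorm(3), b, c, d), "dimension mismatch")
  # zeroed final decoder layer forces zero reconstructions
  net0 <- net
  net0$params$decW2 <- net0$params$decW2 * 0
  net0$params$decb2 <- net0$params$decb2 * 0
  fw0 <- forward_pair(net0, a, b, c, d)
  expect_true(all(fw0$A4 == 0) && all(fw0$D4 == 0))
})

test_that("network constructor validates its configuration", {
  expect_error(paired_autoencoder(4, hidden_dims = integer(0), embed_dim = 2,
                                  n_classes_b1 = 2, n_classes_b2 = 2),
               "non-empty")
  expect_error(paired_autoencoder(4, embed_dim = 8,
                                  n_classes_b1 = 2, n_classes_b2 = 2),
               "smaller")
})

test_that("loss functions reproduce hand-computed values", {
  # reconstruction: one stream fully wrong, the other perfect
  expect_equal(loss_reconstruction(a1 = c(1, 0), c1 = c(0, 1),
                                   b1 = c(2, 2), d1 = c(3, 3),
                                   E2 = rep(0, 4), F2 = c(2, 2, 3, 3),
                                   eps_r = 2), 0.5)
  # structure: A4 vs C4 off by 1 in both coordinates, same cluster
  expect_equal(loss_structure(A4 = c(0, 0), C4 = c(1, 1),
                              B4 = c(0, 0), D4 = c(5, 5),
                              C1_entry = 1, C2_entry = 0, eps_s = 2), 1)
  expect_equal(loss_structure(c(0, 0), c(9, 9), c(1, 1), c(8, 8),
                              0, 0, 2), 0)
  # cluster: weighted squared distance across batches
  expect_equal(loss_cluster(A4 = c(1, 0), B4 = c(0, 0),
                            C4 = c(0, 0), D4 = c(0, 0),
                            M_AB = 1, M_CD = 0, eps_c = 2), 0.5)
  expect_equal(loss_cluster(c(1, 0), c(0, 0), c(0, 0), c(0, 0), 2, 0, 2), 1)
  # prediction: uniform over 2 classes against a one-hot target
  u <- matrix(0.5, 1, 2); y <- matrix(c(1, 0), 1, 2)
  perfect <- y
  expect_equal(loss_prediction(u, perfect, perfect, perfect,
                               y, y, y, y), 0.25)
  expect_equal(loss_prediction(perfect, perfect, perfect, perfect,
                               y, y, y, y), 0)
  expect_equal(total_loss(0.5, 1, 0.5, 0.25), 2.25)
  expect_equal(total_loss(0, 0, 0, 0), 0)
})

test_that("losses match independent naive evaluation on random tensors", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- sample(2:8, 1)
    a <- rnorm(d); b <- rnorm(d); cc <- rnorm(d); dd <- rnorm(d)
    A4 <- rnorm(d); B4 <- rnorm(d); C4 <- rnorm(d); D4 <- rnorm(d)
    c1 <- rbinom(1, 1, 0.5); c2 <- rbinom(1, 1, 0.5)
    mab <- runif(1, 0, 2); mcd <- runif(1, 0, 2)
    expect_equal(loss_reconstruction(a, cc, b, dd, c(A4, C4), c(B4, D4), d),
                 naive_lr(a, cc, b, dd, c(A4, C4), c(B4, D4), d),
                 tolerance = 1e-8)
    expect_equal(loss_structure(A4, C4, B4, D4, c1, c2, d),
                 naive_ls(A4, C4, B4, D4, c1, c2, d), tolerance = 1e-8)
    expect_equal(loss_cluster(A4, B4, C4, D4, mab, mcd, d),
                 naive_lc(A4, B4, C4, D4, mab, mcd, d), tolerance = 1e-8)
    k1 <- sample(2:5, 1); k2 <- sample(2:5, 1)
    ps <- list(rand_simplex(k1), rand_simplex(k2),
               rand_simplex(k1), rand_simplex(k2))
    la <- sample(0:(k1 - 1), 1); lb <- sample(0:(k2 - 1), 1)
    lc <- sample(0:(k1 - 1), 1); ld <- sample(0:(k2 - 1), 1)
    ys <- list(one_hot(la, k1)[1, ], one_hot(lb, k2)[1, ],
               one_hot(lc, k1)[1, ], one_hot(ld, k2)[1, ])
    expect_equal(loss_prediction(matrix(ps[[1]], 1), matrix(ps[[2]], 1),
                                 matrix(ps[[3]], 1), matrix(ps[[4]], 1),
                                 matrix(ys[[1]], 1), matrix(ys[[2]], 1),
                                 matrix(ys[[3]], 1), matrix(ys[[4]], 1)),
                 naive_lp(ps, ys), tolerance = 1e-8)
  }
})

test_that("losses are gated and bounded as the formulas imply", {
  set.seed(20)
  d <- 5
  A4 <- matrix(rnorm(3 * d), 3); B4 <- matrix(rnorm(3 * d), 3)
  C4 <- matrix(rnorm(3 * d), 3); D4 <- matrix(rnorm(3 * d), 3)
  # zero gates kill the structure/cluster terms regardless of values
  expect_equal(loss_structure(A4, C4, B4, D4, rep(0, 3), rep(0, 3), d), 0)
  expect_equal(loss_cluster(A4, B4, C4, D4, rep(0, 3), rep(0, 3), d), 0)
  # doubling a cluster weight doubles its term
  l1 <- loss_cluster(A4, B4, C4, D4, rep(1, 3), rep(0, 3), d)
  l2 <- loss_cluster(A4, B4, C4, D4, rep(2, 3), rep(0, 3), d)
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  # prediction loss bound: ||p - onehot||^2 <= 2 on the simplex
  k <- 4
  P <- t(replicate(3, rand_simplex(k)))
  Y <- one_hot(sample(0:(k - 1), 3, replace = TRUE), k)
  lp <- loss_prediction(P, P, P, P, Y, Y, Y, Y)
  expect_lte(lp, 4 * 2 / k)
  expect_error(one_hot(5L, 4L), "outside")
})
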