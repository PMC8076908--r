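test_that("pair sampling respects stratification contracts", {
  ts <- tiny_setup()
  set.seed(1)
  mb <- sample_pairs(ts$f1, ts$f2, ts$cm, batch_size = 200,
                     frac_matched = 1, frac_intra = 1)
  expect_true(all(mb$mAB > 0))          # every (A,B) pair cluster-matched
  expect_true(all(mb$mCD > 0))
  expect_true(all(mb$cAC == 1))         # every (A,C) pair shares a cluster
  expect_equal(dim(mb$XA), c(200, ts$d))
  # fixed seed reproduces the identical pair stream
  set.seed(42); mb1 <- sample_pairs(ts$f1, ts$f2, ts$cm, 50)
  set.seed(42); mb2 <- sample_pairs(ts$f1, ts$f2, ts$cm, 50)
  expect_identical(mb1, mb2)
})

test_that("matched-pair fraction is honoured binomially", {
  ts <- tiny_setup()
  set.seed(2)
  draws <- 1e4
  mb <- sample_pairs(ts$f1, ts$f2, ts$cm, batch_size = draws,
                     frac_matched = 0.5, frac_intra = 0.5)
  share <- mean(mb$mAB > 0)
  sigma <- sqrt(0.5 * 0.5 / draws)
  expect_lt(abs(share - 0.5), 3 * sigma)
})

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(3)
  d <- 3; B <- 3
  net <- paired_autoencoder(d, hidden_dims = 4, embed_dim = 2,
                            n_classes_b1 = 2, n_classes_b2 = 3, seed = 5)
  mb <- list(XA = matrix(rnorm(B * d), B, d), XB = matrix(rnorm(B * d), B, d),
             XC = matrix(rnorm(B * d), B, d), XD = matrix(rnorm(B * d), B, d),
             cAC = rbinom(B, 1, 0.5), cBD = rbinom(B, 1, 0.5),
             mAB = runif(B), mCD = runif(B),
             la = sample(0:1, B, TRUE), lb = sample(0:2, B, TRUE),
             lc = sample(0:1, B, TRUE), ld = sample(0:2, B, TRUE))
  losses <- cbalign:::ae_losses(net, mb)
  grads <- cbalign:::ae_backward(net, mb, losses)
  lossfun <- function(params) {
    n2 <- net; n2$params <- params
    cbalign:::ae_losses(n2, mb)$total
  }
  h <- 1e-6
  for (nm in names(grads)) {
    num <- net$params[[nm]] * 0
    for (i in seq_along(num)) {
      up <- net$params; up[[nm]][i] <- up[[nm]][i] + h
      dn <- net$params; dn[[nm]][i] <- dn[[nm]][i] - h
      num[i] <- (lossfun(up) - lossfun(dn)) / (2 * h)
    }
    expect_lt(max(abs(num - grads[[nm]])) / max(1, max(abs(num))), 1e-4)
  }
})

test_that("training descends, reproduces bitwise, and records history", {
  ts <- tiny_setup()
  al <- fit_autoencoder(ts$net, ts$f1, ts$f2, ts$cm, max_epochs = 150,
                        batch_size = 64, window = 30, seed = 11)
  h <- al$train_state$history
  expect_equal(nrow(h), al$train_state$epoch)
  expect_true(all(is.finite(as.matrix(h))))
  # smoothed total loss at stop is no worse than at the start
  w <- 30
  expect_lte(mean(utils::tail(h$total, w)), mean(utils::head(h$total, w)))
  al2 <- fit_autoencoder(ts$net, ts$f1, ts$f2, ts$cm, max_epochs = 150,
                         batch_size = 64, window = 30, seed = 11)
  expect_identical(al$train_state$history, al2$train_state$history)
  expect_identical(al$embedding, al2$embedding)
})

test_that("with zero structure/cluster weights the model is a plain paired autoencoder", {
  ts <- tiny_setup()
  net <- paired_autoencoder(ts$d, hidden_dims = 8, embed_dim = 3,
                            n_classes_b1 = 2, n_classes_b2 = 2, seed = 4,
                            loss_weights = c(r = 1, s = 0, c = 0, p = 0))
  al <- fit_autoencoder(net, ts$f1, ts$f2, ts$cm, max_epochs = 400,
                        batch_size = 64, window = 50, seed = 12)
  h <- al$train_state$history
  # reconstruction loss drives the optimum and decreases substantially
  expect_lt(mean(utils::tail(h$Lr, 25)), 0.5 * mean(utils::head(h$Lr, 5)))
})

test_that("batches aligned by construction need no cluster-loss pressure", {
  # with zero batch effect the matched cells are already close, so the
  # (unforced) cluster loss of a model trained without its term stays far
  # below the same quantity on batches with a real technical shift
  run <- function(shift) {
    cfg <- sim_config(n_clusters = 3, cells_per_cluster = 40, n_genes = 200,
                      batch_shift_magnitude = shift, seed = 21)
    sim <- generate_batches(cfg)
    pp <- preprocess_batches(sim$b1, sim$b2, min_cells_per_gene = 3,
                             hvg = list(n_top = 150), n_pcs = 8)
    cm <- cluster_match(pp$f1, pp$f2, seed = 1)
    net <- paired_autoencoder(8, hidden_dims = 16, embed_dim = 6,
                              n_classes_b1 = cm$K1, n_classes_b2 = cm$K2,
                              seed = 2,
                              loss_weights = c(r = 1, s = 1, c = 0, p = 1))
    al <- fit_autoencoder(net, pp$f1, pp$f2, cm, max_epochs = 600,
                          batch_size = 128, window = 100, seed = 3)
    mean(utils::tail(al$train_state$history$Lc, 100))
  }
  expect_lt(run(0), 0.5 * run(20))
})

test_that("cell embeddings are defined for all cells and stabilise with repeats", {
  ts <- tiny_setup()
  al <- embed_cells(ts$net, ts$f1, ts$f2, ts$cm, repeats = 1, seed = 7)
  n <- nrow(ts$f1$values) + nrow(ts$f2$values)
  expect_equal(dim(al$embedding), c(n, ts$net$embed_dim))
  al2 <- embed_cells(ts$net, ts$f1, ts$f2, ts$cm, repeats = 1, seed = 7)
  expect_identical(al$embedding, al2$embedding)   # R = 1 with fixed seed
  # partner averaging reduces run-to-run embedding variance
  spread <- function(repeats) {
    runs <- lapply(1:5, function(s)
      embed_cells(ts$net, ts$f1, ts$f2, ts$cm, repeats = repeats,
                  seed = 100 + s)$embedding)
    mean(apply(simplify2array(runs), c(1, 2), stats::var))
  }
  expect_lt(spread(16), spread(1))
})

test_that("unmatched batch-2 clusters still receive embeddings", {
  ts <- tiny_setup()
  cm <- ts$cm
  # force both batch-1 clusters onto batch-2 cluster 0; cluster 1 unmatched
  cm$match <- c(0L, 0L)
  al <- embed_cells(ts$net, ts$f1, ts$f2, cm, repeats = 2, seed = 8)
  expect_true(all(is.finite(al$embedding)))
})
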