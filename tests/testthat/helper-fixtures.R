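# small in-code fixtures shared across test files

make_batch <- function(counts, tag = "b1", labels = NULL) {
  colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  expression_batch(counts, colnames(counts),
                   paste0(tag, "_c", seq_len(nrow(counts))), tag,
                   provided_labels = labels)
}

# two well-separated Gaussian blobs in `d` dimensions
blob_features <- function(n_per = 100, d = 5, sep = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep), n_per, d))
  list(x = x, labels = rep(0:1, each = n_per))
}

# random labeled features for cluster-match fixtures
random_features <- function(n, d, K, seed) {
  set.seed(seed)
  list(x = matrix(rnorm(n * d, sd = 2), n, d),
       labels = sample(0:(K - 1), n, replace = TRUE))
}

# a tiny trained-size network and matched fixture for training tests
tiny_setup <- function(seed = 3, n = 60, d = 4, K = 2) {
  set.seed(seed)
  x1 <- matrix(rnorm(n * d), n, d) + 2 * (seq_len(n) > n / 2)
  x2 <- matrix(rnorm(n * d), n, d) + 2 * (seq_len(n) > n / 2)
  l1 <- as.integer(seq_len(n) > n / 2)
  l2 <- as.integer(seq_len(n) > n / 2)
  f1 <- feature_matrix(x1, "b1")
  f2 <- feature_matrix(x2, "b2")
  cm <- cluster_match(f1, f2, labels1 = l1, labels2 = l2)
  net <- paired_autoencoder(d, hidden_dims = 8, embed_dim = 3,
                            n_classes_b1 = K, n_classes_b2 = K, seed = seed)
  list(f1 = f1, f2 = f2, cm = cm, net = net, d = d)
}
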