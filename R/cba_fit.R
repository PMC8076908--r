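#' Cluster-guided alignment of two scRNA-seq batches
#'
#' The main fitting function. Runs the full pipeline on two raw-count
#' batches: preprocessing (cluster-size and gene filters, total-count log
#' normalization, joint HVG selection, joint PCA), independent Louvain
#' clustering of each batch, cross-batch cluster matching by log mean cosine
#' distance, and training of the shared-weight paired autoencoder under the
#' composite loss (reconstruction + structure-preserving + cluster-preserving
#' + cluster prediction). The aligned embedding, one row per cell of both
#' batches, is the encoder output averaged over random matched partners.
#'
#' @param b1,b2 Raw-count [expression_batch()] objects.
#' @param min_cluster_cells,min_cells_per_gene,scale,n_pcs,hvg Preprocessing
#'   controls, see [preprocess_batches()].
#' @param resolution Louvain resolution (scalar or per-batch length 2).
#' @param n_neighbors kNN graph size for clustering.
#' @param hidden_dims,embed_dim Network architecture, see
#'   [paired_autoencoder()].
#' @param loss_weights Named weights of the four loss terms (default all 1).
#' @param lr,max_epochs,batch_size,window,tol,frac_matched,frac_intra
#'   Training controls, see [fit_autoencoder()].
#' @param embed_repeats Partner repeats when reading out per-cell embeddings.
#' @param seed Single seed behind every random choice (clustering, weight
#'   initialization, pair sampling, partner choice).
#' @param verbose Progress-line frequency in epochs (0 = silent).
#' @return Object of class `cba_fit`. Key fields: `embedding` (all cells x
#'   `embed_dim`), `batch_of_cell`, `cluster_match`, `alignment` (the
#'   [fit_autoencoder()] result), `features` (the pre-alignment PCA
#'   embedding), `n_pcs`, `call`.
#' @examples
#' \donttest{
#' sim <- generate_batches(sim_config(n_clusters = 3, cells_per_cluster = 40,
#'                                    n_genes = 200, seed = 1))
#' fit <- cba_align(sim$b1, sim$b2, min_cells_per_gene = 3, n_pcs = 8,
#'                  hidden_dims = 32, embed_dim = 8, max_epochs = 300,
#'                  seed = 1)
#' fit
#' }
#' @export
cba_align <- function(b1, b2, min_cluster_cells = 10,
                      min_cells_per_gene = c(50, 50), scale = 1e4,
                      n_pcs = NULL, hvg = list(), resolution = 1,
                      n_neighbors = 15, hidden_dims = c(512), embed_dim = 128,
                      loss_weights = c(r = 1, s = 1, c = 1, p = 1),
                      lr = 5e-4, max_epochs = 10000, batch_size = 256,
                      window = 100, tol = 1e-4, frac_matched = 0.75,
                      frac_intra = 0.75, embed_repeats = 16, seed = 0,
                      verbose = 0) {
  cl <- match.call()
  pp <- preprocess_batches(b1, b2, min_cluster_cells = min_cluster_cells,
                           min_cells_per_gene = min_cells_per_gene,
                           scale = scale, n_pcs = n_pcs, hvg = hvg)
  cm <- cluster_match(pp$f1, pp$f2, resolution = resolution, seed = seed,
                      n_neighbors = n_neighbors)
  net <- paired_autoencoder(pp$n_pcs, hidden_dims = hidden_dims,
                            embed_dim = min(embed_dim, 2 * pp$n_pcs - 1),
                            n_classes_b1 = cm$K1, n_classes_b2 = cm$K2,
                            seed = seed, loss_weights = loss_weights)
  al <- fit_autoencoder(net, pp$f1, pp$f2, cm, lr = lr,
                        max_epochs = max_epochs, batch_size = batch_size,
                        window = window, tol = tol,
                        frac_matched = frac_matched, frac_intra = frac_intra,
                        embed_repeats = embed_repeats, seed = seed,
                        verbose = verbose)
  structure(list(embedding = al$embedding,
                 batch_of_cell = al$batch_of_cell,
                 cluster_match = cm, alignment = al,
                 features = list(f1 = pp$f1, f2 = pp$f2),
                 hvg_genes = pp$hvg_genes, n_pcs = pp$n_pcs,
                 variance_ratio = pp$variance_ratio,
                 seed = seed, call = cl),
            class = "cba_fit")
}

#' @export
print.cba_fit <- function(x, ...) {
  cat("Cluster-guided batch alignment\n")
  cat("Call: "); print(x$call)
  n1 <- sum(x$batch_of_cell == x$batch_of_cell[1])
  cat(sprintf("  %d + %d cells, %d HVGs, %d PCs, embedding dim %d\n",
              n1, length(x$batch_of_cell) - n1, length(x$hvg_genes),
              x$n_pcs, ncol(x$embedding)))
  print(x$cluster_match)
  ts <- x$alignment$train_state
  cat(sprintf("  trained %d epochs%s; final losses Lr=%.4f Ls=%.4f Lc=%.4f Lp=%.4f\n",
              ts$epoch, if (ts$stopped_early) " (early stop)" else "",
              utils::tail(ts$history$Lr, 1), utils::tail(ts$history$Ls, 1),
              utils::tail(ts$history$Lc, 1), utils::tail(ts$history$Lp, 1)))
  invisible(x)
}

#' Summarize an alignment fit
#'
#' Prints the fit and, when requested, the five integration metrics of the
#' aligned embedding via [evaluate_alignment()].
#'
#' @param object A [cba_align()] fit.
#' @param metrics Compute the evaluation metrics (default `TRUE`).
#' @param ... Passed to [evaluate_alignment()].
#' @return Invisibly, a list with the training state and (optionally) the
#'   evaluation report.
#' @export
summary.cba_fit <- function(object, metrics = TRUE, ...) {
  print(object)
  rep <- NULL
  if (metrics) {
    rep <- evaluate_alignment(object$embedding, object$batch_of_cell,
                              object$cluster_match$labels1,
                              object$cluster_match$labels2,
                              seed = object$seed, ...)
    print(rep)
  }
  invisible(list(train_state = object$alignment$train_state, report = rep))
}

#' @export
fitted.cba_fit <- function(object, ...) object$alignment$reconstructions

#' @export
residuals.cba_fit <- function(object, ...) {
  object$alignment$inputs - object$alignment$reconstructions
}

#' Extract or compute aligned embeddings
#'
#' With no new data, returns the aligned embedding of the training cells.
#' With `newdata` (a [feature_matrix()] in the same PC space, or a plain
#' matrix) and a `batch` index, embeds the new cells by pairing them with
#' matched-cluster partners from the training data of the other batch.
#'
#' @param object A [cba_align()] fit.
#' @param newdata Optional feature matrix of new cells.
#' @param batch Which batch the new cells belong to (1 or 2).
#' @param repeats Partner repeats for the averaging.
#' @param ... Unused.
#' @return Numeric matrix of embedding coordinates.
#' @export
predict.cba_fit <- function(object, newdata = NULL, batch = 1, repeats = 16,
                            ...) {
  if (is.null(newdata)) return(object$embedding)
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else as.matrix(newdata)
  net <- object$alignment$net
  cm <- object$cluster_match
  f1 <- object$features$f1; f2 <- object$features$f2
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(object$seed + 2)
  n <- nrow(x)
  E <- matrix(0, n, net$embed_dim)
  other <- if (batch == 1) f2$values else f1$values
  for (r in seq_len(repeats)) {
    p <- sample.int(nrow(other), n, replace = TRUE)
    Z <- if (batch == 1) cbind(x, other[p, , drop = FALSE])
         else cbind(other[p, , drop = FALSE], x)
    E <- E + encode_pairs(net, Z)
  }
  E / repeats
}

#' Plot an alignment fit
#'
#' Scatter of the first two embedding coordinates, coloured by batch (default)
#' or by cluster, plus the loss history.
#'
#' @param x A [cba_align()] fit.
#' @param which `"embedding"`, `"loss"` or both (default).
#' @param color `"batch"` or `"cluster"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cba_fit <- function(x, which = c("embedding", "loss"),
                         color = c("batch", "cluster"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  color <- match.arg(color)
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if ("embedding" %in% which) {
    grp <- if (color == "batch") factor(x$batch_of_cell)
           else factor(c(x$cluster_match$labels1, x$cluster_match$labels2))
    graphics::plot(x$embedding[, 1], x$embedding[, 2],
                   col = as.integer(grp), pch = 16, cex = 0.6,
                   xlab = "embedding 1", ylab = "embedding 2",
                   main = "aligned embedding", ...)
    graphics::legend("topright", legend = levels(grp),
                     col = seq_along(levels(grp)), pch = 16, cex = 0.7)
  }
  if ("loss" %in% which) {
    h <- x$alignment$train_state$history
    graphics::matplot(seq_len(nrow(h)), h[, c("Lr", "Ls", "Lc", "Lp")],
                      type = "l", lty = 1, xlab = "epoch", ylab = "loss",
                      main = "training losses")
    graphics::legend("topright", legend = c("Lr", "Ls", "Lc", "Lp"),
                     col = 1:4, lty = 1, cex = 0.7)
  }
  invisible(x)
}
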