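#' Construct the paired autoencoder
#'
#' A two-stream autoencoder with shared weights: each stream encodes the
#' concatenation of one batch-1 cell and one batch-2 cell through stacked
#' dense layers (leaky-ReLU) to a low-dimensional embedding, then decodes it
#' back to the concatenated input dimension. A linear + softmax classifier
#' head per batch predicts a cell's cluster from its reconstruction.
#'
#' @param input_dim Number of features per cell (the PC dimension).
#' @param hidden_dims Sizes of the hidden dense layers on each side of the
#'   embedding (default `c(512)`, mirrored in the decoder).
#' @param embed_dim Embedding dimension (default 128); must be smaller than
#'   `2 * input_dim`.
#' @param n_classes_b1,n_classes_b2 Cluster counts of the two batches (sizes
#'   of the classifier heads).
#' @param seed Seed for the Glorot-uniform weight initialization.
#' @param leak Negative slope of the leaky-ReLU (default 0.01).
#' @param loss_weights Named numeric weights for the four loss terms
#'   (`r`, `s`, `c`, `p`); the reference formulation is unweighted.
#' @return Object of class `paired_autoencoder`.
#' @export
paired_autoencoder <- function(input_dim, hidden_dims = c(512),
                               embed_dim = 128, n_classes_b1, n_classes_b2,
                               seed = 0, leak = 0.01,
                               loss_weights = c(r = 1, s = 1, c = 1, p = 1)) {
  if (length(hidden_dims) < 1) stop("hidden_dims must be non-empty")
  if (embed_dim >= 2 * input_dim)
    stop("embed_dim must be smaller than 2 * input_dim")
  enc_dims <- c(2 * input_dim, hidden_dims, embed_dim)
  dec_dims <- c(embed_dim, rev(hidden_dims), 2 * input_dim)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  params <- list()
  init <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  for (l in seq_len(length(enc_dims) - 1)) {
    params[[paste0("encW", l)]] <- init(enc_dims[l], enc_dims[l + 1])
    params[[paste0("encb", l)]] <- numeric(enc_dims[l + 1])
  }
  for (l in seq_len(length(dec_dims) - 1)) {
    params[[paste0("decW", l)]] <- init(dec_dims[l], dec_dims[l + 1])
    params[[paste0("decb", l)]] <- numeric(dec_dims[l + 1])
  }
  params$cls1W <- init(input_dim, n_classes_b1)
  params$cls1b <- numeric(n_classes_b1)
  params$cls2W <- init(input_dim, n_classes_b2)
  params$cls2b <- numeric(n_classes_b2)
  structure(list(params = params, input_dim = input_dim,
                 hidden_dims = hidden_dims, embed_dim = embed_dim,
                 n_classes_b1 = n_classes_b1, n_classes_b2 = n_classes_b2,
                 n_enc = length(enc_dims) - 1, n_dec = length(dec_dims) - 1,
                 leak = leak,
                 loss_weights = loss_weights, seed = as.integer(seed)),
            class = "paired_autoencoder")
}

#' @export
print.paired_autoencoder <- function(x, ...) {
  cat(sprintf("<paired_autoencoder>: %d -> [%s] -> %d (shared two-stream)\n",
              2 * x$input_dim, paste(x$hidden_dims, collapse = ","),
              x$embed_dim))
  cat(sprintf("  classifier heads: %d / %d classes\n",
              x$n_classes_b1, x$n_classes_b2))
  invisible(x)
}

lrelu <- function(x, leak) ifelse(x > 0, x, leak * x)
lrelu_grad <- function(x, leak) ifelse(x > 0, 1, leak)

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

#' One-hot encode integer labels
#'
#' @param labels 0-based integer labels.
#' @param n_classes Number of classes.
#' @return Binary matrix, length(labels) x n_classes.
#' @export
one_hot <- function(labels, n_classes) {
  if (any(labels < 0 | labels >= n_classes))
    stop("label index outside class count")
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

# run a stacked dense block; linear output layer, leaky-ReLU elsewhere.
# Returns activations (H[[1]] is the input) and pre-activations for backprop.
mlp_forward <- function(params, prefix, nlayers, X, leak) {
  H <- vector("list", nlayers + 1); P <- vector("list", nlayers)
  H[[1]] <- X
  for (l in seq_len(nlayers)) {
    pre <- H[[l]] %*% params[[paste0(prefix, "W", l)]]
    pre <- sweep(pre, 2, params[[paste0(prefix, "b", l)]], "+")
    P[[l]] <- pre
    H[[l + 1]] <- if (l == nlayers) pre else lrelu(pre, leak)
  }
  list(H = H, pre = P)
}

# backprop through a dense block; returns gradient wrt the block input and
# accumulates parameter gradients into `grads` (an environment-free list).
mlp_backward <- function(params, prefix, nlayers, fwd, dOut, leak, grads) {
  dH <- dOut
  for (l in rev(seq_len(nlayers))) {
    dpre <- if (l == nlayers) dH else dH * lrelu_grad(fwd$pre[[l]], leak)
    nmW <- paste0(prefix, "W", l); nmb <- paste0(prefix, "b", l)
    gW <- crossprod(fwd$H[[l]], dpre)
    gb <- colSums(dpre)
    grads[[nmW]] <- if (is.null(grads[[nmW]])) gW else grads[[nmW]] + gW
    grads[[nmb]] <- if (is.null(grads[[nmb]])) gb else grads[[nmb]] + gb
    dH <- tcrossprod(dpre, params[[nmW]])
  }
  list(dIn = dH, grads = grads)
}

as_row_matrix <- function(x, d) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

#' Forward pass of the paired autoencoder
#'
#' Encodes the cross-batch pairs (a1, b1) and (c1, d1) through the shared
#' encoder into the embeddings `Mvec` and `Nvec`, decodes them into the
#' reconstructions A4..D4, assembles the same-batch concatenations
#' `E2 = A4 || C4` and `F2 = B4 || D4`, and applies the classifier heads to
#' the reconstructions.
#'
#' @param net A [paired_autoencoder()].
#' @param a1,c1 Batch-1 input vectors or row-matrices (`input_dim` features).
#' @param b1,d1 Batch-2 input vectors or row-matrices.
#' @return List with `Mvec`, `Nvec`, `A4`, `B4`, `C4`, `D4`, `E2`, `F2` and
#'   `class_probs` (softmax outputs for each of the four cells).
#' @export
forward_pair <- function(net, a1, b1, c1, d1) {
  d <- net$input_dim
  a1 <- as_row_matrix(a1, d); b1 <- as_row_matrix(b1, d)
  c1 <- as_row_matrix(c1, d); d1 <- as_row_matrix(d1, d)
  if (ncol(a1) != d || ncol(b1) != d || ncol(c1) != d || ncol(d1) != d)
    stop("dimension mismatch: inputs must have input_dim features")
  p <- net$params
  enc1 <- mlp_forward(p, "enc", net$n_enc, cbind(a1, b1), net$leak)
  enc2 <- mlp_forward(p, "enc", net$n_enc, cbind(c1, d1), net$leak)
  Mvec <- enc1$H[[net$n_enc + 1]]
  Nvec <- enc2$H[[net$n_enc + 1]]
  dec1 <- mlp_forward(p, "dec", net$n_dec, Mvec, net$leak)
  dec2 <- mlp_forward(p, "dec", net$n_dec, Nvec, net$leak)
  R1 <- dec1$H[[net$n_dec + 1]]; R2 <- dec2$H[[net$n_dec + 1]]
  A4 <- R1[, 1:d, drop = FALSE];      B4 <- R1[, (d + 1):(2 * d), drop = FALSE]
  C4 <- R2[, 1:d, drop = FALSE];      D4 <- R2[, (d + 1):(2 * d), drop = FALSE]
  probs <- list(
    A = softmax_rows(sweep(A4 %*% p$cls1W, 2, p$cls1b, "+")),
    B = softmax_rows(sweep(B4 %*% p$cls2W, 2, p$cls2b, "+")),
    C = softmax_rows(sweep(C4 %*% p$cls1W, 2, p$cls1b, "+")),
    D = softmax_rows(sweep(D4 %*% p$cls2W, 2, p$cls2b, "+")))
  list(Mvec = Mvec, Nvec = Nvec, A4 = A4, B4 = B4, C4 = C4, D4 = D4,
       E2 = cbind(A4, C4), F2 = cbind(B4, D4), class_probs = probs,
       caches = list(enc1 = enc1, enc2 = enc2, dec1 = dec1, dec2 = dec2))
}

#' Reconstruction loss
#'
#' Mean over pair quadruples of
#' `(1/(2 eps_r)) * sum((a1||c1 - E2)^2) + (1/(2 eps_r)) * sum((b1||d1 - F2)^2)`,
#' comparing each batch's concatenated inputs with the corresponding
#' concatenated reconstructions.
#'
#' @param a1,c1,b1,d1 Input row-matrices (`eps_r` features each).
#' @param E2,F2 Concatenated reconstructions (`2 * eps_r` columns).
#' @param eps_r Features per cell.
#' @return Non-negative scalar.
#' @export
loss_reconstruction <- function(a1, c1, b1, d1, E2, F2, eps_r) {
  a1 <- as_row_matrix(a1, eps_r); c1 <- as_row_matrix(c1, eps_r)
  b1 <- as_row_matrix(b1, eps_r); d1 <- as_row_matrix(d1, eps_r)
  E2 <- as_row_matrix(E2, 2 * eps_r); F2 <- as_row_matrix(F2, 2 * eps_r)
  per <- rowSums((cbind(a1, c1) - E2)^2) / (2 * eps_r) +
         rowSums((cbind(b1, d1) - F2)^2) / (2 * eps_r)
  mean(per)
}

#' Structure-preserving loss
#'
#' Penalises distance between same-batch reconstructions gated by the
#' within-batch same-cluster indicators:
#' `(1/eps_s) * sum((A4-C4)^2) * C1 + (1/eps_s) * sum((B4-D4)^2) * C2`.
#'
#' @param A4,C4,B4,D4 Reconstruction row-matrices.
#' @param C1_entry,C2_entry Same-cluster indicators (0/1), one per row.
#' @param eps_s Features per cell.
#' @return Non-negative scalar.
#' @export
loss_structure <- function(A4, C4, B4, D4, C1_entry, C2_entry, eps_s) {
  A4 <- as_row_matrix(A4, eps_s); C4 <- as_row_matrix(C4, eps_s)
  B4 <- as_row_matrix(B4, eps_s); D4 <- as_row_matrix(D4, eps_s)
  per <- rowSums((A4 - C4)^2) * C1_entry / eps_s +
         rowSums((B4 - D4)^2) * C2_entry / eps_s
  mean(per)
}

#' Cluster-preserving loss
#'
#' Penalises distance between cross-batch reconstructions weighted by the
#' matched-cluster weights:
#' `(1/eps_c) * sum((A4-B4)^2) * M_AB + (1/eps_c) * sum((C4-D4)^2) * M_CD`.
#'
#' @param A4,B4,C4,D4 Reconstruction row-matrices.
#' @param M_AB,M_CD Non-negative matched-cluster weights, one per row.
#' @param eps_c Features per cell.
#' @return Non-negative scalar.
#' @export
loss_cluster <- function(A4, B4, C4, D4, M_AB, M_CD, eps_c) {
  A4 <- as_row_matrix(A4, eps_c); B4 <- as_row_matrix(B4, eps_c)
  C4 <- as_row_matrix(C4, eps_c); D4 <- as_row_matrix(D4, eps_c)
  per <- rowSums((A4 - B4)^2) * M_AB / eps_c +
         rowSums((C4 - D4)^2) * M_CD / eps_c
  mean(per)
}

#' Cluster prediction loss
#'
#' Squared error between each cell's softmax class probabilities and its
#' one-hot cluster label, summed over the four cells of a quadruple. The
#' normalizer of each term is the class count of the relevant head.
#'
#' @param probs_a,probs_b,probs_c,probs_d Softmax output row-matrices.
#' @param onehot_a,onehot_b,onehot_c,onehot_d Matching one-hot label matrices.
#' @return Non-negative scalar.
#' @export
loss_prediction <- function(probs_a, probs_b, probs_c, probs_d,
                            onehot_a, onehot_b, onehot_c, onehot_d) {
  term <- function(p, y) {
    p <- as.matrix(p); y <- as.matrix(y)
    if (!all(dim(p) == dim(y))) stop("label index outside class count")
    rowSums((p - y)^2) / ncol(p)
  }
  mean(term(probs_a, onehot_a) + term(probs_b, onehot_b) +
       term(probs_c, onehot_c) + term(probs_d, onehot_d))
}

#' Total training loss
#'
#' Unweighted sum of the reconstruction, structure-preserving,
#' cluster-preserving and cluster prediction losses.
#'
#' @param Lr,Ls,Lc,Lp Non-negative loss values.
#' @return `Lr + Ls + Lc + Lp`.
#' @export
total_loss <- function(Lr, Ls, Lc, Lp) Lr + Ls + Lc + Lp

# Forward + all four losses on one minibatch. `mb` carries XA..XD (row
# matrices), gates cAC/cBD/mAB/mCD and 0-based labels la/lb/lc/ld.
ae_losses <- function(net, mb, fwd = NULL) {
  if (is.null(fwd)) fwd <- forward_pair(net, mb$XA, mb$XB, mb$XC, mb$XD)
  d <- net$input_dim
  Lr <- loss_reconstruction(mb$XA, mb$XC, mb$XB, mb$XD, fwd$E2, fwd$F2, d)
  Ls <- loss_structure(fwd$A4, fwd$C4, fwd$B4, fwd$D4, mb$cAC, mb$cBD, d)
  Lc <- loss_cluster(fwd$A4, fwd$B4, fwd$C4, fwd$D4, mb$mAB, mb$mCD, d)
  Lp <- loss_prediction(fwd$class_probs$A, fwd$class_probs$B,
                        fwd$class_probs$C, fwd$class_probs$D,
                        one_hot(mb$la, net$n_classes_b1),
                        one_hot(mb$lb, net$n_classes_b2),
                        one_hot(mb$lc, net$n_classes_b1),
                        one_hot(mb$ld, net$n_classes_b2))
  w <- net$loss_weights
  list(Lr = Lr, Ls = Ls, Lc = Lc, Lp = Lp,
       total = w["r"] * Lr + w["s"] * Ls + w["c"] * Lc + w["p"] * Lp,
       fwd = fwd)
}

# gradient of the softmax squared-error term wrt the pre-softmax scores
softmax_sq_grad <- function(P, Y, scale) {
  G <- P * (P - Y)
  scale * (G - P * rowSums(G))
}

# Analytic gradients of the (weighted) total loss wrt all parameters.
ae_backward <- function(net, mb, losses) {
  fwd <- losses$fwd
  p <- net$params
  d <- net$input_dim
  B <- nrow(fwd$A4)
  w <- net$loss_weights
  grads <- list()
  # d(total)/d(reconstructions)
  dA4 <- w["r"] * (fwd$A4 - mb$XA) / (B * d) +
         w["s"] * 2 * mb$cAC * (fwd$A4 - fwd$C4) / (B * d) +
         w["c"] * 2 * mb$mAB * (fwd$A4 - fwd$B4) / (B * d)
  dC4 <- w["r"] * (fwd$C4 - mb$XC) / (B * d) -
         w["s"] * 2 * mb$cAC * (fwd$A4 - fwd$C4) / (B * d) +
         w["c"] * 2 * mb$mCD * (fwd$C4 - fwd$D4) / (B * d)
  dB4 <- w["r"] * (fwd$B4 - mb$XB) / (B * d) +
         w["s"] * 2 * mb$cBD * (fwd$B4 - fwd$D4) / (B * d) -
         w["c"] * 2 * mb$mAB * (fwd$A4 - fwd$B4) / (B * d)
  dD4 <- w["r"] * (fwd$D4 - mb$XD) / (B * d) -
         w["s"] * 2 * mb$cBD * (fwd$B4 - fwd$D4) / (B * d) -
         w["c"] * 2 * mb$mCD * (fwd$C4 - fwd$D4) / (B * d)
  # classifier heads
  add_head <- function(X4, P, labels, Wnm, bnm, K, dX) {
    Y <- one_hot(labels, K)
    dS <- softmax_sq_grad(P, Y, w["p"] * 2 / (B * K))
    grads[[Wnm]] <<- if (is.null(grads[[Wnm]])) crossprod(X4, dS)
                     else grads[[Wnm]] + crossprod(X4, dS)
    grads[[bnm]] <<- if (is.null(grads[[bnm]])) colSums(dS)
                     else grads[[bnm]] + colSums(dS)
    dX + tcrossprod(dS, p[[Wnm]])
  }
  dA4 <- add_head(fwd$A4, fwd$class_probs$A, mb$la, "cls1W", "cls1b",
                  net$n_classes_b1, dA4)
  dC4 <- add_head(fwd$C4, fwd$class_probs$C, mb$lc, "cls1W", "cls1b",
                  net$n_classes_b1, dC4)
  dB4 <- add_head(fwd$B4, fwd$class_probs$B, mb$lb, "cls2W", "cls2b",
                  net$n_classes_b2, dB4)
  dD4 <- add_head(fwd$D4, fwd$class_probs$D, mb$ld, "cls2W", "cls2b",
                  net$n_classes_b2, dD4)
  # stream 1 (A,B) and stream 2 (C,D) through the shared decoder/encoder
  bk1 <- mlp_backward(p, "dec", net$n_dec, fwd$caches$dec1, cbind(dA4, dB4),
                      net$leak, grads)
  bk2 <- mlp_backward(p, "dec", net$n_dec, fwd$caches$dec2, cbind(dC4, dD4),
                      net$leak, bk1$grads)
  bk3 <- mlp_backward(p, "enc", net$n_enc, fwd$caches$enc1, bk1$dIn,
                      net$leak, bk2$grads)
  bk4 <- mlp_backward(p, "enc", net$n_enc, fwd$caches$enc2, bk2$dIn,
                      net$leak, bk3$grads)
  bk4$grads
}
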