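# grouped sampling: one draw per element from the member list of its group
sample_from_groups <- function(group_of_elem, members_list) {
  out <- integer(length(group_of_elem))
  for (g in unique(group_of_elem)) {
    idx <- which(group_of_elem == g)
    mem <- members_list[[as.character(g)]]
    out[idx] <- mem[sample.int(length(mem), length(idx), replace = TRUE)]
  }
  out
}

#' Sample training quadruples
#'
#' Draws a minibatch of (A, B, C, D) cell quadruples: A and C from batch 1,
#' B and D from batch 2. Sampling is stratified: with probability
#' `frac_intra`, C is drawn from A's cluster (likewise D for C via the batch-2
#' pairing below); with probability `frac_matched`, B is drawn from the
#' cluster matched to A's cluster, and otherwise from a non-matched cluster
#' (likewise D with respect to C). Stratification keeps the gated structure
#' and cluster losses supplied with non-zero pairs. The per-pair gate weights
#' are attached.
#'
#' @param f1,f2 [feature_matrix()] objects.
#' @param cm A [cluster_match()].
#' @param batch_size Number of quadruples.
#' @param frac_matched Fraction of cross-batch pairs forced into matched
#'   clusters (default 0.75).
#' @param frac_intra Fraction of same-batch pairs forced into one cluster
#'   (default 0.75).
#' @return List with input matrices `XA`, `XB`, `XC`, `XD`, gates `cAC`,
#'   `cBD`, `mAB`, `mCD`, labels `la`, `lb`, `lc`, `ld`, and the sampled cell
#'   indices.
#' @export
sample_pairs <- function(f1, f2, cm, batch_size = 256,
                         frac_matched = 0.75, frac_intra = 0.75) {
  x1 <- f1$values; x2 <- f2$values
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 == 0 || n2 == 0) stop("both batches must be non-empty")
  l1 <- cm$labels1; l2 <- cm$labels2
  k1 <- sort(unique(l1)); k2 <- sort(unique(l2))
  members1 <- split(seq_len(n1), l1)
  members2 <- split(seq_len(n2), l2)
  mm <- cm$match
  have_match <- any(cm$M > 0)
  if (!have_match)
    warning("no matched pairs with positive weight; falling back to uniform sampling")

  iA <- sample.int(n1, batch_size, replace = TRUE)
  # C: same cluster as A with prob frac_intra
  intra <- stats::runif(batch_size) < frac_intra
  iC <- sample.int(n1, batch_size, replace = TRUE)
  if (any(intra))
    iC[intra] <- sample_from_groups(l1[iA[intra]], members1)

  draw_cross <- function(iSrc) {
    matched <- stats::runif(batch_size) < frac_matched
    out <- sample.int(n2, batch_size, replace = TRUE)
    if (!have_match) return(out)
    jm <- mm[base::match(l1[iSrc], k1)]       # matched batch-2 cluster per draw
    for (b in which(matched))
      out[b] <- { mem <- members2[[as.character(jm[b])]]
                  mem[sample.int(length(mem), 1)] }
    for (b in which(!matched)) {
      pool <- which(l2 != jm[b])
      if (length(pool)) out[b] <- pool[sample.int(length(pool), 1)]
    }
    out
  }
  iB <- draw_cross(iA)
  iD <- draw_cross(iC)

  list(XA = x1[iA, , drop = FALSE], XB = x2[iB, , drop = FALSE],
       XC = x1[iC, , drop = FALSE], XD = x2[iD, , drop = FALSE],
       cAC = as.numeric(l1[iA] == l1[iC]),
       cBD = as.numeric(l2[iB] == l2[iD]),
       mAB = cm$M[cbind(iA, iB)], mCD = cm$M[cbind(iC, iD)],
       la = l1[iA], lb = l2[iB], lc = l1[iC], ld = l2[iD],
       idx = list(A = iA, B = iB, C = iC, D = iD))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the paired autoencoder
#'
#' Minibatch Adam optimization of the composite loss. One epoch is
#' `steps_per_epoch` minibatch updates; per-epoch averages of the four loss
#' terms are recorded. Training stops early when the moving average (window
#' `window`) of the total loss has not improved by a relative `tol` for
#' `window` consecutive epochs, or at `max_epochs`.
#'
#' @param net A [paired_autoencoder()].
#' @param f1,f2 Feature matrices of the two batches.
#' @param cm A [cluster_match()] built on the same features.
#' @param lr Adam learning rate (default 5e-4).
#' @param max_epochs Upper bound on epochs (default 10000).
#' @param batch_size Minibatch size (default 256).
#' @param steps_per_epoch Minibatch updates per epoch; default scales with the
#'   data so an epoch sees roughly every cell once.
#' @param frac_matched,frac_intra Stratification fractions for
#'   [sample_pairs()].
#' @param window Moving-average / patience window in epochs (default 100).
#' @param tol Relative improvement threshold (default 1e-4).
#' @param seed Seed covering sampling (weight init is seeded by the network).
#' @param embed_repeats Partner repeats for the final [embed_cells()] call.
#' @param verbose Print a progress line every `verbose` epochs (0 = silent).
#' @return An `alignment_result`: aligned embedding for every cell of both
#'   batches, per-cell reconstructions, loss history and the trained network.
#' @export
fit_autoencoder <- function(net, f1, f2, cm, lr = 5e-4, max_epochs = 10000,
                            batch_size = 256, steps_per_epoch = NULL,
                            frac_matched = 0.75, frac_intra = 0.75,
                            window = 100, tol = 1e-4, seed = 0,
                            embed_repeats = 16, verbose = 0) {
  n1 <- nrow(f1$values); n2 <- nrow(f2$values)
  if (is.null(steps_per_epoch))
    steps_per_epoch <- max(1L, as.integer(floor((n1 + n2) / (2 * batch_size))))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  state <- adam_init(net$params)
  hist <- matrix(NA_real_, max_epochs, 5,
                 dimnames = list(NULL, c("Lr", "Ls", "Lc", "Lp", "total")))
  best <- Inf; stall <- 0L; stopped_early <- FALSE; epoch <- 0L
  for (e in seq_len(max_epochs)) {
    acc <- numeric(5)
    for (s in seq_len(steps_per_epoch)) {
      mb <- sample_pairs(f1, f2, cm, batch_size, frac_matched, frac_intra)
      losses <- ae_losses(net, mb)
      vals <- c(losses$Lr, losses$Ls, losses$Lc, losses$Lp, losses$total)
      if (!all(is.finite(vals))) {
        bad <- c("Lr", "Ls", "Lc", "Lp", "total")[!is.finite(vals)][1]
        stop("non-finite loss during training: ", bad)
      }
      grads <- ae_backward(net, mb, losses)
      upd <- adam_step(net$params, grads, state, lr)
      net$params <- upd$params; state <- upd$state
      acc <- acc + vals
    }
    hist[e, ] <- acc / steps_per_epoch
    epoch <- e
    if (verbose > 0 && e %% verbose == 0)
      message(sprintf("epoch %d  Lr=%.4f Ls=%.4f Lc=%.4f Lp=%.4f total=%.4f",
                      e, hist[e, 1], hist[e, 2], hist[e, 3], hist[e, 4],
                      hist[e, 5]))
    if (e >= window) {
      smoothed <- mean(hist[(e - window + 1):e, "total"])
      if (smoothed < best * (1 - tol)) { best <- smoothed; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= window) { stopped_early <- TRUE; break }
    }
  }
  hist <- hist[seq_len(epoch), , drop = FALSE]
  train_state <- list(epoch = epoch, history = as.data.frame(hist),
                      rng_seed = as.integer(seed),
                      stopped_early = stopped_early)
  res <- embed_cells(net, f1, f2, cm, repeats = embed_repeats, seed = seed + 1)
  res$train_state <- train_state
  res$net <- net
  res
}

encode_pairs <- function(net, X) {
  mlp_forward(net$params, "enc", net$n_enc, X, net$leak)$H[[net$n_enc + 1]]
}
decode_embed <- function(net, E) {
  mlp_forward(net$params, "dec", net$n_dec, E, net$leak)$H[[net$n_dec + 1]]
}

#' Embed all cells of both batches
#'
#' The encoder consumes cross-batch pairs, so a single cell is embedded by
#' pairing it with partners from its matched cluster in the other batch and
#' averaging the embedding over `repeats` random partners. Batch-2 cells in a
#' cluster matched by no batch-1 cluster get uniform batch-1 partners (the
#' embedding is still defined). Reconstructions (the cell's own half of the
#' decoder output) are averaged the same way.
#'
#' @param net A trained [paired_autoencoder()].
#' @param f1,f2 Feature matrices.
#' @param cm The [cluster_match()] used in training.
#' @param repeats Number of random partners to average over (default 16).
#' @param seed Seed for partner choice.
#' @return An object of class `alignment_result` with fields `embedding`
#'   (`(n1+n2) x embed_dim`), `reconstructions`, `batch_of_cell`, `cell_ids`.
#' @export
embed_cells <- function(net, f1, f2, cm, repeats = 16, seed = 0) {
  x1 <- f1$values; x2 <- f2$values
  n1 <- nrow(x1); n2 <- nrow(x2)
  l1 <- cm$labels1; l2 <- cm$labels2
  k1 <- sort(unique(l1)); k2 <- sort(unique(l2))
  mm <- cm$match
  members2 <- split(seq_len(n2), l2)
  # batch-1 partners for a batch-2 cell: cells of clusters matched to it
  partners_for_j <- lapply(k2, function(j) {
    src <- k1[which(mm == j)]
    if (length(src)) which(l1 %in% src) else seq_len(n1)
  })
  names(partners_for_j) <- as.character(k2)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  E1 <- matrix(0, n1, net$embed_dim); R1 <- matrix(0, n1, net$input_dim)
  E2 <- matrix(0, n2, net$embed_dim); R2 <- matrix(0, n2, net$input_dim)
  d <- net$input_dim
  for (r in seq_len(repeats)) {
    p1 <- sample_from_groups(mm[base::match(l1, k1)], members2)
    Z <- cbind(x1, x2[p1, , drop = FALSE])
    emb <- encode_pairs(net, Z)
    rec <- decode_embed(net, emb)
    E1 <- E1 + emb; R1 <- R1 + rec[, 1:d, drop = FALSE]
    p2 <- sample_from_groups(l2, partners_for_j)
    Z <- cbind(x1[p2, , drop = FALSE], x2)
    emb <- encode_pairs(net, Z)
    rec <- decode_embed(net, emb)
    E2 <- E2 + emb; R2 <- R2 + rec[, (d + 1):(2 * d), drop = FALSE]
  }
  embedding <- rbind(E1, E2) / repeats
  recon <- rbind(R1, R2) / repeats
  ids <- c(if (is.null(f1$cell_ids)) paste0("b1_", seq_len(n1)) else f1$cell_ids,
           if (is.null(f2$cell_ids)) paste0("b2_", seq_len(n2)) else f2$cell_ids)
  rownames(embedding) <- ids
  structure(list(embedding = embedding, reconstructions = recon,
                 batch_of_cell = c(rep(f1$source_batch, n1),
                                   rep(f2$source_batch, n2)),
                 cell_ids = ids, inputs = rbind(x1, x2),
                 cluster_labels = c(l1, l2),
                 train_state = NULL, net = net),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result>: %d cells embedded in %d dimensions\n",
              nrow(x$embedding), ncol(x$embedding)))
  if (!is.null(x$train_state))
    cat(sprintf("  trained %d epochs%s; final total loss %.4f\n",
                x$train_state$epoch,
                if (x$train_state$stopped_early) " (early stop)" else "",
                utils::tail(x$train_state$history$total, 1)))
  invisible(x)
}
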