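#' Configuration for the synthetic two-batch generator
#'
#' Describes a two-batch scRNA-seq simulation: K shared Gaussian-mixture
#' clusters in a latent expression space, a linear map to gene space, an
#' additive per-batch technical shift in (log) gene space, negative-binomial
#' count noise with cell-specific library sizes, and optional perturbations —
#' a batch-exclusive subcluster inside one shared cluster, or a cluster
#' deleted from one batch.
#'
#' @param n_clusters Number of shared clusters.
#' @param cells_per_cluster Cells per cluster per batch (scalar or length-2
#'   list/vector per batch).
#' @param n_genes Number of genes.
#' @param latent_dim Latent dimensionality.
#' @param cluster_separation Radius of the sphere the cluster means are drawn
#'   on, in units of the (unit) within-cluster latent standard deviation.
#' @param batch_shift_magnitude L2 norm of the additive batch shift in log
#'   gene space (applied to batch 2; 0 means no batch effect).
#' @param subcluster_spec Optional list `(cluster, batch, magnitude,
#'   fraction)`: offset `fraction` of the host cluster's cells in one batch by
#'   a latent vector of the given magnitude.
#' @param dropped_cluster Optional list `(cluster, batch)`: remove one cluster
#'   from one batch.
#' @param library_size Expected total counts per cell.
#' @param noise_dispersion Negative-binomial dispersion (1/size); larger is
#'   noisier.
#' @param seed Seed making the generator bit-reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 4, cells_per_cluster = 75, n_genes = 500,
                       latent_dim = 10, cluster_separation = 5,
                       batch_shift_magnitude = 20, subcluster_spec = NULL,
                       dropped_cluster = NULL, library_size = 2000,
                       noise_dispersion = 0.3, seed = 0) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              cells_per_cluster = cells_per_cluster,
              n_genes = as.integer(n_genes),
              latent_dim = as.integer(latent_dim),
              cluster_separation = cluster_separation,
              batch_shift_magnitude = batch_shift_magnitude,
              subcluster_spec = subcluster_spec,
              dropped_cluster = dropped_cluster,
              library_size = library_size,
              noise_dispersion = noise_dispersion,
              seed = as.integer(seed))
  stopifnot(cfg$n_clusters >= 1, cfg$n_genes >= 2, cfg$latent_dim >= 1,
            cfg$cluster_separation > 0, cfg$batch_shift_magnitude >= 0,
            cfg$library_size > 0, cfg$noise_dispersion >= 0)
  if (!is.null(cfg$subcluster_spec))
    stopifnot(cfg$subcluster_spec$cluster %in% (seq_len(cfg$n_clusters) - 1L),
              cfg$subcluster_spec$batch %in% 1:2,
              cfg$subcluster_spec$magnitude >= 0,
              cfg$subcluster_spec$fraction > 0, cfg$subcluster_spec$fraction <= 1)
  if (!is.null(cfg$dropped_cluster))
    stopifnot(cfg$dropped_cluster$cluster %in% (seq_len(cfg$n_clusters) - 1L),
              cfg$dropped_cluster$batch %in% 1:2)
  structure(cfg, class = "sim_config")
}

#' Generate two synthetic batches
#'
#' Draws cluster means on a sphere of radius `cluster_separation` in latent
#' space, latent cell positions as mean + standard-normal noise, maps them to
#' log gene space through a shared random loading matrix, adds the per-batch
#' shift vector, converts to negative-binomial counts whose per-cell expected
#' totals equal a lognormal library size, and applies the optional subcluster
#' and dropped-cluster perturbations.
#'
#' @param config A [sim_config()].
#' @return List with `b1`, `b2` ([expression_batch()] objects, raw counts)
#'   and `truth` (per-cell true cluster id, subcluster flag, and the applied
#'   per-batch shift vectors).
#' @export
generate_batches <- function(config) {
  cfg <- config
  cpc <- cfg$cells_per_cluster
  if (length(cpc) == 1) cpc <- c(cpc, cpc)
  if (any(unlist(cpc) < 1)) stop("infeasible config: zero cells per cluster")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  K <- cfg$n_clusters; L <- cfg$latent_dim; G <- cfg$n_genes
  # cluster means on a sphere of radius cluster_separation
  mu <- matrix(stats::rnorm(K * L), K, L)
  mu <- mu / sqrt(rowSums(mu^2)) * cfg$cluster_separation
  loadings <- matrix(stats::rnorm(G * L, sd = 1 / sqrt(L)), G, L)
  baseline <- stats::rnorm(G, mean = 0, sd = 0.5)
  shift_dir <- stats::rnorm(G)
  shift <- shift_dir / sqrt(sum(shift_dir^2)) * cfg$batch_shift_magnitude
  shifts <- list(b1 = numeric(G), b2 = shift)
  sub_dir <- stats::rnorm(L)
  sub_dir <- sub_dir / sqrt(sum(sub_dir^2))

  make_batch <- function(bi) {
    keep_k <- seq_len(K) - 1L
    if (!is.null(cfg$dropped_cluster) && cfg$dropped_cluster$batch == bi)
      keep_k <- setdiff(keep_k, cfg$dropped_cluster$cluster)
    ncell <- cpc[[bi]]
    labels <- rep(keep_k, each = ncell)
    n <- length(labels)
    Z <- mu[labels + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * L), n, L)
    subflag <- rep(FALSE, n)
    sc <- cfg$subcluster_spec
    if (!is.null(sc) && sc$batch == bi && sc$cluster %in% keep_k) {
      host <- which(labels == sc$cluster)
      pick <- host[seq_len(max(1, round(length(host) * sc$fraction)))]
      Z[pick, ] <- Z[pick, ] + rep(sub_dir * sc$magnitude, each = length(pick))
      subflag[pick] <- TRUE
    }
    eta <- Z %*% t(loadings) + rep(baseline, each = n) +
      rep(shifts[[bi]], each = n)
    # per-cell expected totals: lognormal library sizes around the target
    lib <- cfg$library_size * stats::rlnorm(n, -0.125^2 / 2, 0.125)
    rate <- exp(eta)
    mu_counts <- rate / rowSums(rate) * lib
    counts <- matrix(
      if (cfg$noise_dispersion > 0)
        stats::rnbinom(n * G, mu = as.vector(mu_counts),
                       size = 1 / cfg$noise_dispersion)
      else stats::rpois(n * G, as.vector(mu_counts)),
      n, G)
    colnames(counts) <- paste0("gene", seq_len(G))
    list(batch = expression_batch(counts, paste0("gene", seq_len(G)),
                                  paste0("batch", bi, "_cell", seq_len(n)),
                                  paste0("batch", bi)),
         labels = labels, subflag = subflag)
  }
  r1 <- make_batch(1); r2 <- make_batch(2)
  truth <- list(cluster1 = r1$labels, cluster2 = r2$labels,
                subcluster1 = r1$subflag, subcluster2 = r2$subflag,
                shifts = shifts)
  list(b1 = r1$batch, b2 = r2$batch, truth = truth)
}

#' Named scenario presets
#'
#' Three deterministic configurations mirroring the evaluation scenarios:
#' `"pancreas-like"` (shared clusters, moderate technical shift),
#' `"subcluster"` (a batch-1-exclusive subpopulation inside one shared
#' cluster) and `"missing-type"` (one cluster absent from batch 1).
#'
#' @return Named list of [sim_config()] objects.
#' @export
scenario_presets <- function() {
  list(
    "pancreas-like" = sim_config(
      n_clusters = 4, cells_per_cluster = 75, n_genes = 500, latent_dim = 10,
      cluster_separation = 5, batch_shift_magnitude = 20,
      library_size = 2000, noise_dispersion = 0.3, seed = 0),
    "subcluster" = sim_config(
      n_clusters = 4, cells_per_cluster = 75, n_genes = 500, latent_dim = 10,
      cluster_separation = 5, batch_shift_magnitude = 20,
      subcluster_spec = list(cluster = 0L, batch = 1L, magnitude = 4,
                             fraction = 0.4),
      library_size = 2000, noise_dispersion = 0.3, seed = 0),
    "missing-type" = sim_config(
      n_clusters = 4, cells_per_cluster = 75, n_genes = 500, latent_dim = 10,
      cluster_separation = 5, batch_shift_magnitude = 20,
      dropped_cluster = list(cluster = 3L, batch = 1L),
      library_size = 2000, noise_dispersion = 0.3, seed = 0))
}

#' Serialize / restore a simulation config
#'
#' Round-trips a [sim_config()] through a YAML file so preset definitions can
#' be shared with the command-line interface.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_sim_config()` returns the restored [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
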