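#' Run a simulated alignment scenario end to end
#'
#' Generates a two-batch dataset from a [sim_config()] (or a named preset from
#' [scenario_presets()]), runs the complete alignment pipeline with the
#' desk-scale study configuration (300 HVGs on 500 simulated genes, scree-elbow
#' PC choice, a 64-unit hidden layer with a 16-dimensional embedding), and
#' returns the simulation, the fit and the pre/post batch-mixing rejection
#' rates.
#'
#' @param config A [sim_config()] or the name of a preset.
#' @param seed Seed for clustering, initialization and training.
#' @param resolution Louvain resolution (scalar or per-batch length 2).
#' @param ... Further arguments to [cba_align()] (e.g. `max_epochs`).
#' @return List with `sim` (generator output), `fit` (the [cba_align()]
#'   object), `truth` (per-cell true cluster ids across both batches),
#'   `kbet_unaligned` and `kbet_aligned`.
#' @export
run_scenario <- function(config, seed = 0, resolution = 1, ...) {
  if (is.character(config)) config <- scenario_presets()[[config]]
  if (is.null(config)) stop("unknown scenario preset")
  sim <- generate_batches(config)
  fit <- cba_align(sim$b1, sim$b2, min_cells_per_gene = 3,
                   hvg = list(n_top = 300), resolution = resolution,
                   hidden_dims = 64, embed_dim = 16, seed = seed, ...)
  tags <- fit$batch_of_cell
  unaligned <- rbind(fit$features$f1$values, fit$features$f2$values)
  list(sim = sim, fit = fit,
       truth = c(sim$truth$cluster1, sim$truth$cluster2),
       kbet_unaligned = kbet_rejection(unaligned, tags),
       kbet_aligned = kbet_rejection(fit$embedding, tags))
}
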