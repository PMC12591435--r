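#' Simulation benchmark over replicated datasets
#'
#' Reproduces one cell of the simulation study: generates `reps` ground-truth
#' networks and datasets for a given structure/weighting/size, runs the full
#' recovery pipeline on each, and scores both credible-level selectors
#' (estimated-F1 maximization and target-FDR control) against the truth.
#' Both selectors share one GEM fit and one permutation curve per replicate,
#' so the extra selector is free. Replicate r uses the deterministic child
#' seed `seed + r`, so runs are reproducible and order-independent.
#'
#' @param structure `"scale_free"` or `"cluster"`.
#' @param weights `"fixed"` or `"random"` partial-correlation scheme.
#' @param p,n Number of variables and samples.
#' @param reps Number of replicated datasets.
#' @param alpha Passed to [hmf_network()] (`"cc"`, `"heuristic"`, or a
#'   number).
#' @param beta Off-diagonal shrinkage weight.
#' @param n_perm Permutation replicates per dataset.
#' @param fdr_target Target for the FDR selector.
#' @param seed Master seed.
#' @param density Within-cluster density for `structure = "cluster"`
#'   (default: the generator's calibrated scheme default).
#' @return A data frame, one row per replicate and selector, with columns
#'   `structure`, `weights`, `p`, `n`, `rep`, `seed`, `alpha_mode`, `alpha`,
#'   `selector`, `gamma`, `n_edges`, `mcc`, `f1`, `fdr`, `tpr`, `acc`,
#'   `nmi` (NA for scale-free), `true_acc`.
#' @export
benchmark_cell <- function(structure = c("scale_free", "cluster"),
                           weights = c("fixed", "random"),
                           p = 100L, n = 300L, reps = 50L,
                           alpha = "cc", beta = 0.9, n_perm = 50L,
                           fdr_target = 0.2, seed = 1L, density = NULL) {
  structure <- match.arg(structure)
  weights <- match.arg(weights)
  rows <- vector("list", 2L * reps)
  for (r in seq_len(reps)) {
    rep_seed <- as.integer(seed) + r
    net <- if (structure == "scale_free") {
      generate_scale_free(p, weights = weights, seed = rep_seed)
    } else {
      generate_cluster(p, weights = weights, density = density, seed = rep_seed)
    }
    Y <- sample_mvn(net, n = n, seed = rep_seed + 500000L)
    res_f1 <- hmf_network(Y, alpha = alpha, beta = beta, selection = "f1",
                          n_perm = n_perm, seed = rep_seed + 1000000L)
    # reuse the fit and permutation curve for the FDR selector
    pick <- gamma_for_target_fdr(res_f1$fp_curve$edge_counts,
                                 res_f1$fp_curve$fp_hat,
                                 res_f1$fp_curve$gamma, fdr_target)
    adj_fdr <- adjacency_at_gamma(res_f1$fit$omega,
                                  sqrt(edge_variances(res_f1$fit)),
                                  pick$gamma)
    true_acc <- average_clustering_coefficient(net$adjacency)
    row_for <- function(selector, adj_hat, gamma_sel) {
      m <- evaluate_network(adj_hat, net)
      data.frame(structure = structure, weights = weights, p = p, n = n,
                 rep = r, seed = rep_seed, alpha_mode = res_f1$alpha_mode,
                 alpha = res_f1$alpha, selector = selector,
                 gamma = gamma_sel, n_edges = sum(adj_hat) / 2,
                 mcc = m$mcc, f1 = m$f1, fdr = m$fdr, tpr = m$tpr,
                 acc = m$acc, nmi = if (is.null(m$nmi)) NA_real_ else m$nmi,
                 true_acc = true_acc)
    }
    rows[[2L * r - 1L]] <- row_for("f1", res_f1$adjacency, res_f1$gamma)
    rows[[2L * r]] <- row_for("fdr", adj_fdr, pick$gamma)
  }
  do.call(rbind, rows)
}

#' Run a grid of benchmark cells
#'
#' Applies [benchmark_cell()] to every row of a grid and aggregates the
#' per-replicate results, returning both the raw rows and the per-cell means
#' and standard deviations of all metrics.
#'
#' @param grid Data frame with columns `structure`, `weights`, `p`, `n`, and
#'   optionally `reps`, `alpha`, `n_perm`.
#' @param reps,alpha,beta,n_perm,fdr_target,seed Defaults for columns the
#'   grid omits.
#' @return List with `raw` (per-replicate data frame) and `summary` (one row
#'   per cell, selector and metric-set, columns `<metric>_mean`,
#'   `<metric>_sd`).
#' @export
run_benchmark <- function(grid, reps = 50L, alpha = "cc", beta = 0.9,
                          n_perm = 50L, fdr_target = 0.2, seed = 1L) {
  stopifnot(is.data.frame(grid), all(c("structure", "weights", "p", "n") %in% names(grid)))
  raw <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    benchmark_cell(
      structure = as.character(g$structure), weights = as.character(g$weights),
      p = g$p, n = g$n,
      reps = if ("reps" %in% names(grid)) g$reps else reps,
      alpha = if ("alpha" %in% names(grid)) g$alpha else alpha,
      beta = beta,
      n_perm = if ("n_perm" %in% names(grid)) g$n_perm else n_perm,
      fdr_target = fdr_target,
      seed = as.integer(seed) + 10000L * i)
  }))
  metrics <- c("mcc", "f1", "fdr", "tpr", "acc", "nmi", "true_acc")
  keys <- c("structure", "weights", "p", "n", "alpha_mode", "selector")
  agg_mean <- stats::aggregate(raw[metrics], raw[keys], mean, na.rm = TRUE)
  agg_sd <- stats::aggregate(raw[metrics], raw[keys], stats::sd, na.rm = TRUE)
  names(agg_mean)[match(metrics, names(agg_mean))] <- paste0(metrics, "_mean")
  names(agg_sd)[match(metrics, names(agg_sd))] <- paste0(metrics, "_sd")
  list(raw = raw, summary = merge(agg_mean, agg_sd, by = keys))
}
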