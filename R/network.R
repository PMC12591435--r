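#' Recover a sparse partial-correlation network end to end
#'
#' The full workflow: (optional) nonparanormal transform, standardization,
#' shrinkage-weight selection (CC method, heuristic, or fixed), GEM fit,
#' permutation false-positive curve, credible-level selection (estimated-F1
#' maximization, target-FDR control, or a fixed level), and the resulting
#' adjacency matrix. Deterministic for a fixed seed.
#'
#' @param Y Numeric samples-by-variables matrix (or data frame).
#' @param alpha `"cc"` (condition-number constraint, the default),
#'   `"heuristic"` (\eqn{10p/(10p+n)}, cluster-friendly), or a fixed numeric
#'   value in `[0, 1)`.
#' @param beta Off-diagonal shrinkage weight (default 0.9).
#' @param selection `"f1"` (maximize permutation-estimated F1, the default),
#'   `"fdr"` (smallest credible level meeting `fdr_target`), or `"fixed"`
#'   (use `gamma` directly, no permutations).
#' @param fdr_target Target FDR for `selection = "fdr"` (default 0.2).
#' @param gamma Credible mass for `selection = "fixed"` (default 0.95).
#' @param K Expected number of true edges for the F1 selector; default `p`.
#' @param n_perm Number of permutation replicates (default 50).
#' @param seed Master seed for the permutation streams.
#' @param standardize Scale columns to unit SD (default `TRUE`).
#' @param nonparanormal Apply [nonparanormal_transform()] first (default
#'   `FALSE`).
#' @param control Further convergence controls; `alpha`/`beta` fields are
#'   overridden by the arguments above.
#' @return An object of class `"hmf_network"`: list with `adjacency`,
#'   `gamma` (selected credible mass), `fit` (the `"hmf_fit"`), `fp_curve`
#'   (`NULL` for fixed selection), `selection`, `alpha_mode`, `alpha`,
#'   `alpha_search` (the CC search object when used), `n_edges`, `seed`,
#'   and selector details (`fdr_hat` or `f1_hat`).
#' @seealso [tidy.hmf_network()], [write_network()]
#' @export
#' @examples
#' net <- generate_scale_free(p = 15, seed = 1)
#' Y <- sample_mvn(net, n = 100, seed = 2)
#' res <- hmf_network(Y, alpha = 0.3, selection = "f1", n_perm = 10, seed = 3)
#' res$n_edges
hmf_network <- function(Y, alpha = "cc", beta = 0.9,
                        selection = c("f1", "fdr", "fixed"),
                        fdr_target = 0.2, gamma = 0.95, K = NULL,
                        n_perm = 50L, seed = 1L,
                        standardize = TRUE, nonparanormal = FALSE,
                        control = hmf_control(beta = beta)) {
  selection <- match.arg(selection)
  Y <- as.matrix(Y)
  if (nrow(Y) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (nonparanormal) Y <- nonparanormal_transform(Y)
  moments <- sample_moments(Y, standardize = standardize)
  control$beta <- beta

  alpha_search <- NULL
  if (identical(alpha, "cc")) {
    alpha_search <- select_alpha_cc(moments, control)
    alpha_val <- alpha_search$alpha_hat
    fit <- alpha_search$fit
    alpha_mode <- "cc"
  } else if (identical(alpha, "heuristic")) {
    alpha_val <- alpha_heuristic(moments$n, moments$p)
    control$alpha <- alpha_val
    fit <- gem_fit(moments, control)
    alpha_mode <- "heuristic"
  } else if (is.numeric(alpha) && length(alpha) == 1L) {
    alpha_val <- alpha
    control$alpha <- alpha_val
    fit <- gem_fit(moments, control)
    alpha_mode <- "fixed"
  } else {
    stop('`alpha` must be "cc", "heuristic", or a single number', call. = FALSE)
  }

  sd_mat <- sqrt(edge_variances(fit))
  fp_curve <- NULL
  sel_detail <- list()
  if (selection == "fixed") {
    gamma_sel <- gamma
  } else {
    fp_curve <- estimate_fp_curve(fit, n_perm = n_perm, seed = seed)
    if (selection == "fdr") {
      pick <- gamma_for_target_fdr(fp_curve$edge_counts, fp_curve$fp_hat,
                                   fp_curve$gamma, fdr_target)
      sel_detail <- list(fdr_hat = pick$fdr_hat, fdr_target = fdr_target)
    } else {
      if (is.null(K)) K <- moments$p
      pick <- gamma_max_f1(fp_curve$edge_counts, fp_curve$fp_hat,
                           fp_curve$gamma, K)
      sel_detail <- list(f1_hat = pick$f1_hat, K = K)
    }
    gamma_sel <- pick$gamma
  }

  adjacency <- adjacency_at_gamma(fit$omega, sd_mat, gamma_sel)
  dimnames(adjacency) <- list(colnames(Y), colnames(Y))

  structure(
    c(list(adjacency = adjacency, gamma = gamma_sel, fit = fit,
           fp_curve = fp_curve, selection = selection,
           alpha_mode = alpha_mode, alpha = alpha_val,
           alpha_search = alpha_search,
           n_edges = sum(adjacency) / 2, seed = as.integer(seed)),
      sel_detail),
    class = "hmf_network")
}

#' @export
print.hmf_network <- function(x, ...) {
  cat("Recovered partial-correlation network\n")
  cat(sprintf("  p = %d, n = %d; alpha = %.4g (%s), beta = %g\n",
              x$fit$moments$p, x$fit$moments$n, x$alpha, x$alpha_mode,
              x$fit$control$beta))
  cat(sprintf("  credible level gamma = %.4g (%s selection): %d edges\n",
              x$gamma, x$selection, x$n_edges))
  if (!is.null(x$fdr_hat)) {
    cat(sprintf("  estimated FDR %.3g (target %.3g)\n", x$fdr_hat, x$fdr_target))
  }
  if (!is.null(x$f1_hat)) {
    cat(sprintf("  estimated F1 %.3g (K = %d)\n", x$f1_hat, x$K))
  }
  invisible(x)
}

#' Score a recovered network against a ground truth
#'
#' Convenience wrapper: confusion counts plus MCC/F1/FDR/TPR, the average
#' clustering coefficient of the estimate, and (when the truth carries
#' cluster labels) the normalized mutual information between the estimate's
#' communities and the true labels.
#'
#' @param network An `"hmf_network"` (or a bare adjacency matrix).
#' @param truth An `"hmf_true_network"` (or a bare adjacency matrix).
#' @param nmi_method Community-labelling method for NMI, see
#'   [cluster_labels()].
#' @return Named list of metrics.
#' @export
evaluate_network <- function(network, truth, nmi_method = "modularity") {
  adj_hat <- if (inherits(network, "hmf_network")) network$adjacency else network
  labels <- NULL
  if (inherits(truth, "hmf_true_network")) {
    labels <- truth$cluster_labels
    adj_true <- truth$adjacency
  } else {
    adj_true <- truth
  }
  cts <- confusion(adj_hat, adj_true)
  sc <- scores(cts)
  sc$acc <- average_clustering_coefficient(adj_hat)
  if (!is.null(labels)) {
    sc$nmi <- nmi(cluster_labels(adj_hat, method = nmi_method), labels)
  }
  c(sc, cts)
}
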