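#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

as_maybe_tibble <- function(df) {
  if (requireNamespace("tibble", quietly = TRUE)) tibble::as_tibble(df) else df
}

#' Tidy a GEM fit into a per-pair table
#'
#' One row per unordered variable pair, with the MAP estimate, the
#' approximate posterior SD, the implied z-score, and the partial
#' correlation \eqn{-\hat\omega_{ij}/\sqrt{\hat\omega_{ii}\hat\omega_{jj}}}.
#'
#' @param x An `"hmf_fit"`.
#' @param ... Unused.
#' @return A tibble (or data frame) with columns `node_i`, `node_j`,
#'   `omega_hat`, `sd`, `z_score`, `partial_cor`.
#' @export
tidy.hmf_fit <- function(x, ...) {
  p <- x$moments$p
  sd_mat <- sqrt(edge_variances(x))
  up <- which(upper.tri(x$omega), arr.ind = TRUE)
  d <- diag(x$omega)
  nm <- colnames(x$moments$S)
  lab <- function(i) if (is.null(nm)) i else nm[i]
  as_maybe_tibble(data.frame(
    node_i = lab(up[, 1L]), node_j = lab(up[, 2L]),
    omega_hat = x$omega[up],
    sd = sd_mat[up],
    z_score = abs(x$omega[up]) / sd_mat[up],
    partial_cor = -x$omega[up] / sqrt(d[up[, 1L]] * d[up[, 2L]])))
}

#' One-row summary of a GEM fit
#'
#' @param x An `"hmf_fit"`.
#' @param ... Unused.
#' @return A one-row tibble with the hyperparameters, iteration count,
#'   convergence flag and the precision matrix's condition number.
#' @export
glance.hmf_fit <- function(x, ...) {
  as_maybe_tibble(data.frame(
    p = x$moments$p, n = x$moments$n,
    alpha = x$control$alpha, beta = x$control$beta,
    nu = x$nu, delta = x$delta,
    n_iters = x$n_iters, converged = x$converged,
    rel_change = x$rel_change,
    condition_number = condition_number(x$omega)))
}

#' Tidy a recovered network into an edge list
#'
#' One row per selected edge, with the MAP precision entry, its z-score and
#' the implied partial correlation.
#'
#' @param x An `"hmf_network"`.
#' @param ... Unused.
#' @return A tibble (or data frame), zero rows if the graph is empty.
#' @export
tidy.hmf_network <- function(x, ...) {
  tab <- tidy(x$fit)
  z_cut <- stats::qnorm((1 + x$gamma) / 2)
  tab[tab$z_score > z_cut, , drop = FALSE]
}

#' One-row summary of a recovered network
#'
#' @param x An `"hmf_network"`.
#' @param ... Unused.
#' @return A one-row tibble with the shrinkage weights, the selected
#'   credible level, edge count and selector diagnostics.
#' @export
glance.hmf_network <- function(x, ...) {
  as_maybe_tibble(data.frame(
    p = x$fit$moments$p, n = x$fit$moments$n,
    alpha = x$alpha, alpha_mode = x$alpha_mode,
    beta = x$fit$control$beta,
    selection = x$selection, gamma = x$gamma, n_edges = x$n_edges,
    fdr_hat = if (is.null(x$fdr_hat)) NA_real_ else x$fdr_hat,
    f1_hat = if (is.null(x$f1_hat)) NA_real_ else x$f1_hat))
}

#' Tidy a permutation false-positive curve
#'
#' @param x An `"hmf_fp_curve"`.
#' @param ... Unused.
#' @return A tibble (or data frame) with one row per candidate credible
#'   level: `gamma`, `threshold`, `edge_counts`, `fp_hat`, and the implied
#'   `fdr_hat`.
#' @export
tidy.hmf_fp_curve <- function(x, ...) {
  as_maybe_tibble(data.frame(
    gamma = x$gamma, threshold = x$thresholds,
    edge_counts = x$edge_counts, fp_hat = x$fp_hat,
    fdr_hat = ifelse(x$edge_counts > 0, x$fp_hat / x$edge_counts, 0)))
}
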